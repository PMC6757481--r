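# Absorption coefficient of lipid (per unit volume fraction).
# Synthetic digitization: anchor values consistent with published vegetable
# oil / mammalian fat measurements (930 nm band), smoothed.
# species: lipid
# units: mm^-1
# convention: mua
# wavelength_nm value
650 0.00005
700 0.00007
750 0.00030
800 0.00050
850 0.00060
875 0.00080
900 0.00250
915 0.00500
930 0.01100
940 0.00800
950 0.00450
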