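# Absolute NIR extinction of oxidised cytochrome c, static absorption only.
# Synthetic digitization: small, monotonically declining NIR tail.
# species: cytc_oxidised
# units: mM^-1 cm^-1
# convention: decadic
# wavelength_nm value
650 1.00
700 0.80
750 0.65
800 0.55
850 0.50
900 0.45
950 0.40
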