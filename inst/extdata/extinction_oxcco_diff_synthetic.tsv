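# Oxidised-minus-reduced difference extinction spectrum of
# cytochrome-c-oxidase (oxCCO), the spectrum used when unmixing oxidation
# state changes.  Synthetic digitization: broad NIR band centred near 830 nm
# with peak difference extinction ~5.1 mM^-1 cm^-1, following the shape of
# widely reproduced published difference spectra.
# species: oxCCO
# units: mM^-1 cm^-1
# convention: decadic
# wavelength_nm value
650 1.40
675 1.80
700 2.40
725 3.20
750 4.00
775 4.60
800 4.90
820 5.05
830 5.10
840 5.05
860 4.85
880 4.50
900 4.10
925 3.50
950 2.90
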