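# Absolute extinction of oxidised cytochrome-c-oxidase, used only for the
# static (baseline) absorption of the brain layer.  Synthetic digitization:
# smooth broad band consistent in magnitude with published NIR spectra of the
# oxidised enzyme.
# species: CCO_oxidised
# units: mM^-1 cm^-1
# convention: decadic
# wavelength_nm value
650 2.60
700 2.20
750 2.60
800 3.20
830 3.40
850 3.30
900 2.90
950 2.40
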