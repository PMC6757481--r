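# Relative spectral responsivity of a multialkali-cathode photon-counting
# detector.  Synthetic digitization: smooth curve with the characteristic
# monotone decline toward long wavelengths of published multialkali cathode
# responsivity measurements; normalised to 1 at 650 nm.
# species: responsivity
# units: relative
# convention: responsivity
# wavelength_nm value
650 1.000
675 0.970
700 0.920
725 0.850
750 0.760
775 0.650
800 0.530
825 0.420
850 0.310
875 0.210
900 0.130
925 0.075
950 0.040
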