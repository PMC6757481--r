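# Absorption coefficient of pure water (per unit volume fraction).
# Synthetic digitization: anchor values from widely reproduced published
# water absorption measurements, smoothed; percent-level accuracy.
# species: water
# units: mm^-1
# convention: mua
# wavelength_nm value
650 0.00032
675 0.00044
700 0.00060
720 0.00110
730 0.00170
740 0.00226
750 0.00260
760 0.00270
770 0.00258
780 0.00236
790 0.00220
800 0.00206
810 0.00222
820 0.00255
830 0.00290
840 0.00360
850 0.00433
860 0.00460
870 0.00500
880 0.00560
890 0.00620
900 0.00680
910 0.00800
920 0.01100
930 0.01700
940 0.02670
950 0.03880
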