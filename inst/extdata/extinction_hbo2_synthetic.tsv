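# Specific (molar) extinction coefficient of oxyhemoglobin (HbO2).
# Synthetic digitization: node values assembled from widely reproduced
# published compilations of hemoglobin extinction spectra and smoothed;
# accurate at roughly the percent level, not an authoritative copy of any
# single compilation.  See ?nirsSpectra for provenance notes.
# species: HbO2
# units: mM^-1 cm^-1
# convention: decadic
# wavelength_nm value
650 0.368
660 0.320
670 0.294
680 0.278
690 0.276
700 0.290
710 0.314
720 0.342
730 0.390
740 0.446
750 0.518
760 0.586
770 0.650
780 0.710
790 0.756
800 0.816
810 0.864
820 0.916
830 0.974
840 1.022
850 1.058
860 1.092
870 1.128
880 1.154
890 1.190
900 1.198
910 1.210
920 1.214
930 1.214
940 1.214
950 1.204
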