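# Specific (molar) extinction coefficient of deoxyhemoglobin (Hb).
# Synthetic digitization: node values assembled from widely reproduced
# published compilations of hemoglobin extinction spectra and smoothed;
# accurate at roughly the percent level, not an authoritative copy of any
# single compilation.  The 758 nm local band is represented by dense nodes.
# species: Hb
# units: mM^-1 cm^-1
# convention: decadic
# wavelength_nm value
650 3.750
660 3.227
670 2.795
680 2.407
690 2.051
700 1.794
710 1.640
720 1.540
730 1.466
740 1.416
750 1.405
754 1.616
758 1.674
762 1.599
766 1.466
770 1.311
780 1.080
790 0.900
800 0.762
810 0.718
820 0.694
830 0.693
840 0.694
850 0.691
860 0.684
870 0.670
880 0.658
890 0.645
900 0.632
910 0.622
920 0.614
930 0.608
940 0.603
950 0.600
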