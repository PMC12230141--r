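table,comparison,frequency_khz,term,value,ci_lower,ci_upper
agreement,bsa_vs_rms,1,bias,-1.64,-2.72,-0.56
agreement,bsa_vs_rms,1,loa_lower,-8.45,-10.32,-6.57
agreement,bsa_vs_rms,1,loa_upper,5.16,3.29,7.04
agreement,bsa_vs_bootstrap,1,bias,-1.64,-2.74,-0.54
agreement,bsa_vs_bootstrap,1,loa_lower,-8.56,-10.46,-6.65
agreement,bsa_vs_bootstrap,1,loa_upper,5.27,3.37,7.17
agreement,rms_vs_bootstrap,1,bias,0,-1.03,1.03
agreement,rms_vs_bootstrap,1,loa_lower,-6.50,-8.29,-4.71
agreement,rms_vs_bootstrap,1,loa_upper,6.50,4.71,8.29
agreement,bsa_vs_rms,4,bias,-1.66,-3.06,-0.25
agreement,bsa_vs_rms,4,loa_lower,-8.90,-11.34,-6.47
agreement,bsa_vs_rms,4,loa_upper,5.59,3.16,8.03
agreement,bsa_vs_bootstrap,4,bias,-0.52,-1.56,0.52
agreement,bsa_vs_bootstrap,4,loa_lower,-5.88,-7.68,-4.08
agreement,bsa_vs_bootstrap,4,loa_upper,4.84,3.04,6.65
agreement,rms_vs_bootstrap,4,bias,1.60,0.38,2.82
agreement,rms_vs_bootstrap,4,loa_lower,-4.78,-6.88,-2.67
agreement,rms_vs_bootstrap,4,loa_upper,7.98,5.87,10.08
repeatability,rms,1,bias,0.08,-1.59,1.75
repeatability,rms,1,loa_lower,-9.59,-12.48,-6.70
repeatability,rms,1,loa_upper,9.76,6.87,12.65
repeatability,bootstrap,1,bias,-0.26,-1.57,1.06
repeatability,bootstrap,1,loa_lower,-7.77,-10.05,-5.49
repeatability,bootstrap,1,loa_upper,7.26,4.98,9.54
repeatability,rms,4,bias,2.06,-0.08,4.21
repeatability,rms,4,loa_lower,-5.82,-9.54,-2.11
repeatability,rms,4,loa_upper,9.95,6.23,13.66
repeatability,bootstrap,4,bias,-0.19,-2.55,2.17
repeatability,bootstrap,4,loa_lower,-8.87,-12.96,-4.78
repeatability,bootstrap,4,loa_upper,8.50,4.41,12.58
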