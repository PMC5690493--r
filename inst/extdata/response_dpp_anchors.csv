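energy,sdd_mm,relative_sensitivity,source
6X,746,1.012,printed
6X,896,1.000,printed
6X,1196,0.992,printed
10XFFF,746,1.001,printed
10XFFF,896,1.000,printed
10XFFF,1196,0.995,printed
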