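energy,mu_per_min,relative_sensitivity,source
6X,5,0.978,printed
6X,20,0.984,synthetic-fill
6X,50,0.989,synthetic-fill
6X,100,0.993,synthetic-fill
6X,200,0.997,synthetic-fill
6X,400,1.000,printed
6X,600,1.002,synthetic-fill
10XFFF,400,1.000,printed
10XFFF,800,1.001,synthetic-fill
10XFFF,1200,1.002,synthetic-fill
10XFFF,1800,1.003,synthetic-fill
10XFFF,2400,1.004,synthetic-fill
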