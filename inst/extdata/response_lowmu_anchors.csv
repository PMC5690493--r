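setting,position,mu,relative_sensitivity,source
default,entrance,1,0.960,synthetic-fill
default,entrance,2,0.972,printed
default,entrance,5,0.985,synthetic-fill
default,entrance,10,0.992,synthetic-fill
default,entrance,20,0.997,synthetic-fill
default,entrance,50,0.999,synthetic-fill
default,entrance,100,1.000,printed
modified,entrance,1,0.980,synthetic-fill
modified,entrance,2,0.986,derived-half
modified,entrance,5,0.992,synthetic-fill
modified,entrance,10,0.996,synthetic-fill
modified,entrance,20,0.998,synthetic-fill
modified,entrance,50,0.999,synthetic-fill
modified,entrance,100,1.000,printed
default,exit,1,0.920,synthetic-fill
default,exit,2,0.944,synthetic-fill
default,exit,5,0.965,synthetic-fill
default,exit,10,0.980,synthetic-fill
default,exit,20,0.990,synthetic-fill
default,exit,50,0.997,synthetic-fill
default,exit,100,1.000,printed
modified,exit,1,0.960,synthetic-fill
modified,exit,2,0.972,synthetic-fill
modified,exit,5,0.982,synthetic-fill
modified,exit,10,0.990,synthetic-fill
modified,exit,20,0.995,synthetic-fill
modified,exit,50,0.998,synthetic-fill
modified,exit,100,1.000,printed
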