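{"form":"logistic3","coefficients":{"K":0.99,"r":53.8,"Mo":0.528},"ci95":{"K":[0.969,1.01],"r":[45.3,66.3],"Mo":[0.474,0.571]},"clamp_floor":0.5,"loglik":"NA"}
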