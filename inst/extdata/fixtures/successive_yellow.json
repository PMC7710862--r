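{"form":"logistic3","coefficients":{"K":0.951,"r":47.2,"Mo":0.555},"ci95":{"K":[0.913,0.989],"r":[35.7,69.5],"Mo":[0.42,0.651]},"clamp_floor":0.5,"loglik":"NA"}
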