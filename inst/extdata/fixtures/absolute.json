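{"form":"logistic4","coefficients":{"K":0.842,"Mo":0.441,"xmid":0.081,"scal":0.009},"ci95":{"K":[0.766,0.919],"Mo":[0.377,0.505],"xmid":[0.076,0.086],"scal":[0.004,0.015]},"clamp_floor":0.5,"loglik":"NA"}
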