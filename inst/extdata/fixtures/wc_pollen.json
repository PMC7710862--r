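{"margin_x":{"family":"gamma","params":{"shape":182,"rate":159},"se":{"shape":54.9,"rate":48}},"margin_y":{"family":"weibull","params":{"shape":22.8,"scale":1.26},"se":{"shape":3.86,"scale":0.012}},"copula":{"family":"tawn2","rotation":180,"par1":3.61,"par2":0.49,"se":{"par1":0.846,"par2":0.11}}}
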