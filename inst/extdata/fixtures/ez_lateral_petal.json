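{"margin_x":{"family":"normal","params":{"mean":0.761,"std":0.027},"se":{"mean":0.006,"std":0.004}},"margin_y":{"family":"normal","params":{"mean":1.08,"std":0.012},"se":{"mean":0.002,"std":0.002}},"copula":{"family":"joe","rotation":90,"par1":-2.15,"par2":"NA","se":{"par1":0.552}}}
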