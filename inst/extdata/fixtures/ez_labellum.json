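{"margin_x":{"family":"normal","params":{"mean":1.22,"std":0.07},"se":{"mean":0.015,"std":0.011}},"margin_y":{"family":"gamma","params":{"shape":1370,"rate":1100},"se":{"shape":423,"rate":339}},"copula":{"family":"gumbel","rotation":180,"par1":4.19,"par2":"NA","se":{"par1":0.764}}}
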