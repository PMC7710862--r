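{"margin_x":{"family":"gamma","params":{"shape":491,"rate":659},"se":{"shape":136,"rate":183}},"margin_y":{"family":"gamma","params":{"shape":1270,"rate":1150},"se":{"shape":353,"rate":320}},"copula":{"family":"tawn2","rotation":270,"par1":-9.13,"par2":0.244,"se":{"par1":4.75,"par2":0.03}}}
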