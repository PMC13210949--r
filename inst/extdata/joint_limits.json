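{"shoulder":{"type":"euler_box","order":"yxz","lower":[-45,-45,-45],"upper":[150,150,150]},"hip":{"type":"euler_box","order":"yxz","lower":[-45,-45,-45],"upper":[150,150,150]},"elbow":{"type":"hinge","axis":[0,0,1],"lower":5,"upper":150},"knee":{"type":"hinge","axis":[1,0,0],"lower":5,"upper":150}}
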