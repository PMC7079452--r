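layer,r_upper,r_lower
Result,0.98119,NA
HighWay Output,0.98119,0.9300
HighWay Input,0.9300,0.7227
DeMaxPool,0.7227,0.7371
Conv1,0.0090,0.0117
Conv2,0.1627,0.1627
Conv3,-0.0443,-0.0443
Conv4,0.0191,0.0191
Conv5,-0.0984,-0.0984
Conv6,-0.0136,-0.0136
Conv7,0.0806,0.0806
Conv8,0.0957,0.0957
Conv9,0.1528,0.1528
Conv10,0.0845,0.0845
Conv15,0.1038,0.1038
Conv20,0.1851,0.1851
Total,0.98119,0.7398
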