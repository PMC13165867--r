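fold,dice,iou,precision,recall,mae
1,0.9156,0.8452,0.8654,0.8952,0.0598
2,0.9192,0.8501,0.8712,0.9011,0.0574
3,0.9145,0.8438,0.8623,0.8928,0.0612
4,0.9208,0.8529,0.8736,0.9043,0.0561
5,0.9194,0.8508,0.8701,0.9026,0.0579
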