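variant,dice,dice_std,iou,iou_std,precision,recall
Baseline (IncV3),0.8930,0.0031,0.8067,0.0042,0.8744,0.9125
+ MCP,0.9015,0.0028,0.8201,0.0039,0.8792,0.9183
+ ASPP,0.9082,0.0026,0.8320,0.0036,0.8654,0.9256
Full IMAU-Net,0.9179,0.0024,0.8483,0.0035,0.8685,0.8992
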