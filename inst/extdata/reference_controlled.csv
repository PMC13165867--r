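variant,dice,dice_std,iou,precision,recall
InceptionV3 Baseline,0.8912,0.0034,0.8045,0.8720,0.9110
MCP-Net,0.8964,0.0035,0.8152,0.8765,0.9168
ASPP-UNet,0.9031,0.0031,0.8287,0.8680,0.9235
IMAU-Net,0.9152,0.0028,0.8456,0.8785,0.9340
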