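configuration,dice,dice_std,iou
No Preprocessing,0.8743,0.0081,0.7924
CLAHE Only,0.8891,0.0054,0.8112
CLAHE + Denoising,0.9012,0.0042,0.8287
Full Preprocessing,0.9179,0.0024,0.8483
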