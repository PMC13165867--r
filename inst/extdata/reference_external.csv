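metric,internal,external
dice,0.9179,0.8745
iou,0.8483,0.7923
precision,0.8685,0.8592
recall,0.8992,0.8834
hd95,4.23,6.87
auc,0.9783,0.9542
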