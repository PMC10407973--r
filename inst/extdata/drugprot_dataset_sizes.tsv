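dataset	train	development
Original	64779	13480
Augmented	875350	NA
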