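# Indication-for-use vocabulary (one term per line; whole-token,
# case-insensitive matching inside intake posts).
tachycardia
hypertension
high blood pressure
preeclampsia
pre-eclampsia
anxiety
migraine
migraines
cardiomyopathy
svt
palpitations
arrhythmia
heart condition
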