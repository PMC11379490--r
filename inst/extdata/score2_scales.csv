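# SCORE2 region recalibration scales: calibrated risk =
# 1 - exp(-exp(scale1 + scale2 * ln(-ln(1 - uncalibrated risk))))
# (2021 ESC working group publication, supplementary tables)
# version: 1
region,sex,scale1,scale2
low,male,-0.5699,0.7476
low,female,-0.7380,0.7019
moderate,male,-0.1565,0.8009
moderate,female,-0.3143,0.7701
high,male,0.3207,0.9360
high,female,0.5710,0.9369
very_high,male,0.5836,0.8294
very_high,female,0.9412,0.8329
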