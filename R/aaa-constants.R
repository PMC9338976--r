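# Shared vocabulary for the study design: two colon segments, one
# pre-ischemia observation and five post-ischemia observation times
# (minutes after division of the vascular arcade).
TIME_LABELS <- c("pre", "post15", "post45", "post75", "post105", "post135")
POST_LABELS <- TIME_LABELS[-1]
SEGMENTS <- c("right", "left")
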