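# EQ-5D-3L UK social tariff (time trade-off valuation), additive decrement form.
# Transcribed from: Dolan P. Modeling valuations for EuroQol health states.
# Medical Care 1997;35(11):1095-1108 (UK TTO value set).
# transcription_date: 2026-09-25
# checksum: 1997
term,dimension,level,value
constant,,,0.081
decrement,mobility,2,0.069
decrement,mobility,3,0.314
decrement,selfcare,2,0.104
decrement,selfcare,3,0.214
decrement,usual_activities,2,0.036
decrement,usual_activities,3,0.094
decrement,pain_discomfort,2,0.123
decrement,pain_discomfort,3,0.386
decrement,anxiety_depression,2,0.071
decrement,anxiety_depression,3,0.236
decrement,any_level3,,0.269
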