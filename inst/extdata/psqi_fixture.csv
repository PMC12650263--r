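item,response
bedtime,23:30
latency_min,25
waketime,07:00
sleep_hours,6.0
dist_latency,1
dist_wake,2
dist_bathroom,1
dist_breathe,0
dist_cough,0
dist_cold,1
dist_hot,0
dist_dreams,2
dist_pain,0
dist_other,1
quality,2
medication,1
awake_trouble,1
enthusiasm,2
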