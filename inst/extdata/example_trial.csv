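trial_id,arm,n,is_active,ae_term,count
example-1,gabapentin,100,1,dizziness,20
example-1,gabapentin,100,1,headache,6
example-1,gabapentin,100,1,nausea,1
example-1,gabapentin,100,1,fatigue,3
example-1,placebo,100,0,dizziness,5
example-1,placebo,100,0,headache,6
example-1,placebo,100,0,nausea,0
example-1,placebo,100,0,fatigue,2
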