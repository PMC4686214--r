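run_id	tag	condition	replicate
run1	D0	Q7Q7	r1
run1	D3	Q7Q7	r2
run1	D9	Q7Q111	r1
run1	D6	Q111Q111	r1
run1	D12	Q111Q111	r2
run2	D3	Q7Q7	r3
run2	D6	Q7Q7	r4
run2	D0	Q7Q111	r2
run2	D9	Q111Q111	r3
run3	D6	Q7Q7	r5
run3	D9	Q7Q111	r3
run3	D0	Q111Q111	r4
run3	D3	Q111Q111	r5
run4	D6	Q7Q7	r6
run4	D12	Q7Q111	r4
run4	D3	Q7Q111	r5
run4	D9	Q111Q111	r6
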