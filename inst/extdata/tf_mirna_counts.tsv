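mirna	TargetScan	miRanda
miR-27a/miR-27b	5	5
miR-144	3	4
miR-128	3	3
miR-101a/miR-101b	1	4
miR-200a/miR-200b/miR-200c	2	2
miR-124	3	1
miR-103	1	2
miR-106b	1	2
miR-132	1	2
miR-153	1	2
miR-17-5p	1	2
miR-193	1	2
miR-25	1	2
miR-340-5p	1	2
miR-34a/miR-34c	1	2
miR-29a/miR-29b/miR-29c	2	1
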