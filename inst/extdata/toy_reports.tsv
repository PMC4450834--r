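report_id	diagnosis	term_ids
R1	HCC	cirrhosis of liver;splenomegaly
R2	HCC	hepatic fibrosis
R3	NAD	
R4	NAD	fatty liver
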