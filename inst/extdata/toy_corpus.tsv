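abstract_id	text
a01	HCC arising in cirrhosis of liver with portal hypertension.
a02	Hepatocellular carcinoma with hepatic fibrosis and splenomegaly.
a03	Fatty liver disease without malignancy.
a04	HCC presenting as a liver mass; fatty liver noted.
a05	Screening study of hepatic cirrhosis in HCC cohorts.
a06	Splenomegaly in portal hypertension without tumour.
a07	Hepatic fibrosis staging by elastography.
a08	HCC surveillance guidelines.
a09	No abnormality detected on abdominal imaging.
a10	Hepatocellular carcinoma and fatty liver: a case series.
a11	Cirrhosis of liver and splenomegaly co-occurrence study.
a12	HCC with splenomegaly and hepatic cirrhosis.
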