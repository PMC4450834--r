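child_id	parent_id
clinical finding	root concept
finding by site	clinical finding
abdominal finding	finding by site
liver finding	abdominal finding
abdominal organ finding	abdominal finding
fatty liver	abdominal finding
disorder of liver	liver finding
hepatic fibrosis	disorder of liver
cirrhosis of liver	hepatic fibrosis
splenic finding	abdominal organ finding
splenomegaly	splenic finding
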