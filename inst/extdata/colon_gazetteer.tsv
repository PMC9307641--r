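concept_id	preferred_term	synonyms	mapped_class	grade_sensitive
https://example.org/colon#Adenocarcinoma	adenocarcinoma	infiltrating adenocarcinoma|invasive adenocarcinoma|adenocarcinoma of the colon|colorectal adenocarcinoma|mucinous adenocarcinoma	cancer	0
https://example.org/colon#Carcinoma	carcinoma	invasive carcinoma|infiltrating carcinoma|signet ring carcinoma	cancer	0
https://example.org/colon#Cancer	cancer	malignant neoplasm|malignancy	cancer	0
https://example.org/colon#HighGradeDysplasia	high-grade dysplasia	high grade dysplasia|severe dysplasia|marked dysplasia	high_grade_dysplasia	0
https://example.org/colon#LowGradeDysplasia	low-grade dysplasia	low grade dysplasia|mild dysplasia|moderate dysplasia|slight dysplasia	low_grade_dysplasia	0
https://example.org/colon#Dysplasia	dysplasia	dysplastic changes|glandular dysplasia		1
https://example.org/colon#HyperplasticPolyp	hyperplastic polyp	hyperplastic polyps|hyperplasia|hyperplastic mucosa|hyperplastic	hyperplastic_polyp	0
https://example.org/colon#NormalMucosa	normal mucosa	normal colonic mucosa|normal colorectal mucosa|normal glands|regular mucosa|unremarkable mucosa	normal	0
https://example.org/colon#TubularAdenoma	tubular adenoma	tubulovillous adenoma|villous adenoma|adenomatous polyp|adenoma		0
https://example.org/colon#Polyp	polyp	polypectomy|polyps		0
https://example.org/colon#Colon	colon	colorectal|sigmoid colon|rectum|cecum|transverse colon		0
https://example.org/colon#Biopsy	biopsy	biopsies|biopsy fragment|biopsy fragments		0
https://example.org/colon#ResectionMargin	margin of resection	resection margin|surgical margin		0
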