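"code","name","parent","description"
"D1","Leisure entertainment","",""
"D2","Health promotion","",""
"D3","Social interaction","",""
"D4","Self-actualization","",""
"D5","Daily tasks","",""
"D6","Environmental exposure","",""
"C11","Entertainment Venues","D1",""
"C12","Art Viewing Space","D1",""
"C13","Historical & Cultural Sites","D1",""
"C21","Recreation & Fitness Facilities","D2",""
"C22","Healthcare Facilities","D2",""
"C31","Venues for Strong Social Interaction","D3",""
"C32","Multi-Functional Spaces","D3",""
"C41","Intergenerational Activities","D4",""
"C42","Skill Development","D4",""
"C51","Ancestral Worship Sites","D5",""
"C52","Living Convenience Facilities","D5",""
"C53","Transportation & Mobility","D5",""
"C54","Pet-Friendly Facilities","D5",""
"C61","Landscape Vegetation","D6",""
"C62","Acoustic Environment Quality","D6",""
"C63","Ambient Temperature","D6",""
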