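subcategory	pattern
Protein synthesis machinery	ribosom|elongation factor|initiation factor|tRNA synthetase|aminoacyl
Unknown conserved	conserved (protein|hypothetical)|unknown conserved
Transporters and storage	transporter|v-?atpase|vacuolar atpase|channel|ferritin|transferrin
Energy metabolism	cytochrome|nadh|atp synthase|oxidase|dehydrogenase.*(mitochondr|energy)|glycolysis
Protein modification machinery	kinase|phosphatase.*(protein|ser)|chaperon|heat shock|peptidyl|disulfide isomerase|ubiquitin-conjugat
Amino acid metabolism	aminotransferase|amino acid metabol|glutamine synth|arginase
Signal transduction	g[ -]?protein|signal transduc|calmodulin|14-3-3|ras-like
Carbohydrate metabolism	glycogen|glucosidase(?!.*saliv)|aldolase|enolase|phosphoglucose
Protein export machinery	signal recognition particle|sec61|translocon|protein export|signal peptidase
Cytoskeletal	actin|tubulin|myosin|profilin|cofilin
Transcription machinery	rna polymerase|splicing|spliceosome|snrnp|transcription machinery
Lipid metabolism	lipase(?!.*saliv)|fatty acid|lipid metabol|acyl-?coa
Proteasome machinery	proteasome|26s protease|ubiquitin(?!-conjugat)
Extracellular matrix	collagen|laminin|extracellular matrix|peritrophin
Nuclear regulation	histone|nuclear regulation|chromatin
Immunity	lysozyme|defensin|cecropin|gram-negative binding|immune
Intermediate/secondary metabolism	cytochrome p450|glutathione s-transferase|secondary metabol
Nucleic acid metabolism	nucleotidase(?!.*saliv)|nucleic acid metabol|thymidylate|ribonucleotide reductase
Transcription factors	transcription factor|homeobox|zinc finger
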