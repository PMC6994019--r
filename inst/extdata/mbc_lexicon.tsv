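# Recurrent metastatic breast cancer term-to-concept lexicon.
# Columns: surface <TAB> class <TAB> kind <TAB> context_role
# Surfaces are stored verbatim (lowercased); misspellings such as "metastic"
# and "metasteses" are intentional — they occur in real clinical notes.
surface	class	kind	context_role
recurrent metastatic tnbc	DRECUR	target	none
distant relapse	DRECUR	target	none
distant recurrence	DRECUR	target	none
distant recurrences	DRECUR	target	none
distant metastatic disease involving	DRECUR	target	none
regional recurrence	LRECUR	target	none
nodal recurrence	LRECUR	target	none
loco-regional failure	LRECUR	target	none
locally recur	LRECUR	target	none
in-breast recurrence	LRECUR	target	none
local recur	LRECUR	target	none
metastatic breast cancer	MBC	target	none
widespread metastatic breast cancer	MBC	target	none
widely metastatic triple	MBC	target	none
metastatic breast carcinoma	MBC	target	none
metastatic tnbc	MBC	target	none
metastic	MBCLOW	target	none
metasteses	MBCLOW	target	none
metastatis	MBCLOW	target	none
metastatic lobular carcinoma	MBCLOW	target	none
metastatic lesion	MBCLOW	target	none
metastatic lesions	MBCLOW	target	none
metastatic foci	MBCLOW	target	none
mbc	MBCLOW	target	none
met brca	MBCLOW	target	none
bone mets	METSBONE	target	none
bone metastasis	METSBONE	target	none
bone metastases	METSBONE	target	none
bone metasteses	METSBONE	target	none
mets to spine	METSBONE	target	none
boney mets	METSBONE	target	none
diffuse skeletal mets	METSBONE	target	none
osseous metastases	METSBONE	target	none
metastatic disease involving the brain	METSBRAIN	target	none
brain mets	METSBRAIN	target	none
mets to brain	METSBRAIN	target	none
brain metastasis	METSBRAIN	target	none
brain metastases	METSBRAIN	target	none
liver mets	METSLIVER	target	none
liver metastasis	METSLIVER	target	none
liver metastases	METSLIVER	target	none
hepatic mets	METSLIVER	target	none
hepatic metastasis	METSLIVER	target	none
hepatic metastases	METSLIVER	target	none
mets to lung	METSLUNG	target	none
pulm mets	METSLUNG	target	none
lung mets	METSLUNG	target	none
mbc pulm	METSLUNG	target	none
lung metastases	METSLUNG	target	none
pulmonary metastases	METSLUNG	target	none
widespread metastatic disease	METSNOS	target	none
stage4	METSNOS	target	none
newly diagnosed metastatic	METSNOS	target	none
stage iv	METSNOS	target	none
recur	RECUR	target	none
rapid recurrence	RECUR	target	none
multiple recurrences	RECUR	target	none
recurrent disease	RECUR	target	none
reoccurrence	RECUR	target	none
reoccurring	RECUR	target	none
passed away	DIED	target	none
expired on	DIED	target	none
deceased	DIED	target	none
# Context-trigger starter set (NegEx/ConText-style).
no	NEG	context	negation
not	NEG	context	negation
without	NEG	context	negation
denies	NEG	context	negation
denied	NEG	context	negation
no evidence of	NEG	context	negation
no sign of	NEG	context	negation
negative for	NEG	context	negation
absence of	NEG	context	negation
free of	NEG	context	negation
no increase in	PSEUDONEG	context	pseudo_negation
no change in	PSEUDONEG	context	pseudo_negation
no significant change in	PSEUDONEG	context	pseudo_negation
not only	PSEUDONEG	context	pseudo_negation
mother	FAM	context	family
father	FAM	context	family
sister	FAM	context	family
brother	FAM	context	family
aunt	FAM	context	family
grandmother	FAM	context	family
family history	FAM	context	family
maternal	FAM	context	family
if	HYPO	context	hypothetical
rule out	HYPO	context	hypothetical
risk of	HYPO	context	hypothetical
risk for	HYPO	context	hypothetical
concern for	HYPO	context	hypothetical
concerning for	HYPO	context	hypothetical
possible	HYPO	context	hypothetical
possibly	HYPO	context	hypothetical
question of	HYPO	context	hypothetical
may represent	HYPO	context	hypothetical
but	TERM	context	scope_terminator
however	TERM	context	scope_terminator
although	TERM	context	scope_terminator
though	TERM	context	scope_terminator
except	TERM	context	scope_terminator
aside from	TERM	context	scope_terminator
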