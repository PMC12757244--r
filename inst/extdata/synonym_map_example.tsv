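raw_name	standard_name
PROLIA	denosumab
XGEVA	denosumab
DENOSUMAB	denosumab
ZOMETA	zoledronic acid
RECLAST	zoledronic acid
ZOLEDRONIC ACID	zoledronic acid
FOSAMAX	alendronate
ALENDRONATE SODIUM	alendronate
BONIVA	ibandronate
ACTONEL	risedronate
AREDIA	pamidronate
FORTEO	teriparatide
TAXOTERE	docetaxel
TAXOL	paclitaxel
REVLIMID	lenalidomide
AFINITOR	everolimus
IBRANCE	palbociclib
FEMARA	letrozole
DECADRON	dexamethasone
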