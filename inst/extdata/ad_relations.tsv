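relation_class	preferred_relation	surface_form
PATHOLOGY_LINK	IS INVOLVED IN	is involved in
PATHOLOGY_LINK	IS INVOLVED IN	is implicated in
PATHOLOGY_LINK	IS INVOLVED IN	plays a role in
PATHOLOGY_LINK	IS INVOLVED IN	contributes to
PATHOLOGY_LINK	AFFECTS	affects
PATHOLOGY_LINK	CAUSES	causes
PATHOLOGY_LINK	HAS FEATURE	has feature
PATHOLOGY_LINK	LEADS TO	leads to
PATHOLOGY_LINK	RESULTS IN	results in
EXPRESSION	IS EXPRESSED IN	is expressed in
EXPRESSION	IS EXPRESSED IN	is present in
EXPRESSION	IS EXPRESSED IN	is detected in
EXPRESSION	IS EXPRESSED IN	is abundant in
EXPRESSION	EXPRESSES	expresses
EXPRESSION	HAS CONSTITUENT	has constituent
EXPRESSION	IS LOCATION OF	is location of
EXPRESSION	IS LOCATION OF	is the location of
EXPRESSION	IS SITE OF ALTERATION OF	is site of alteration of
UPREGULATION	IS INCREASED IN	is increased in
UPREGULATION	IS INCREASED IN	is elevated in
UPREGULATION	IS INCREASED IN	is raised in
UPREGULATION	IS HIGHER IN	is higher in
UPREGULATION	IS UPREGULATED IN	is upregulated in
UPREGULATION	IS UPREGULATED IN	is up-regulated in
UPREGULATION	HAS UPREGULATED	has upregulated
DISEASE_LINK	IS ASSOCIATED WITH	is associated with
DISEASE_LINK	IS ASSOCIATED WITH	is linked to
DISEASE_LINK	IS ASSOCIATED WITH	is correlated with
DISEASE_LINK	IS RISK FACTOR FOR	is risk factor for
DISEASE_LINK	IS RISK FACTOR FOR	is a risk factor for
DISEASE_LINK	IS ALTERED IN	is altered in
DISEASE_LINK	IS AFFECTED IN	is affected in
PATHWAY_MEMBERSHIP	IS COMPONENT OF	is component of
PATHWAY_MEMBERSHIP	IS COMPONENT OF	is a component of
PATHWAY_MEMBERSHIP	IS MEMBER OF	is member of
PATHWAY_MEMBERSHIP	IS MEMBER OF	is a member of
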