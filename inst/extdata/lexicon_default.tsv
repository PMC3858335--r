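entity_class	surface_form	canonical_id
ETHNICITY	caucasian	Caucasian
ETHNICITY	caucasians	Caucasian
ETHNICITY	european	Caucasian
ETHNICITY	europeans	Caucasian
ETHNICITY	white	Caucasian
ETHNICITY	whites	Caucasian
ETHNICITY	asian	Asian
ETHNICITY	asians	Asian
ETHNICITY	chinese	Asian
ETHNICITY	japanese	Asian
ETHNICITY	korean	Asian
ETHNICITY	koreans	Asian
ETHNICITY	african	African
ETHNICITY	africans	African
ETHNICITY	african american	African
ETHNICITY	african americans	African
ETHNICITY	hispanic	Hispanic
ETHNICITY	hispanics	Hispanic
EFFECT	effect	effect
EFFECT	effects	effect
EFFECT	increase	increase
EFFECT	increased	increase
EFFECT	higher	increase
EFFECT	induction	increase
EFFECT	inducibility	increase
EFFECT	decrease	decrease
EFFECT	decreased	decrease
EFFECT	reduced	decrease
EFFECT	lower	decrease
EFFECT	deficient	no_activity
EFFECT	nonfunctional	no_activity
EFFECT	inactive	no_activity
EFFECT	poor metabolizer	poor_metabolizer
EFFECT	poor metabolizers	poor_metabolizer
EFFECT	extensive metabolizer	extensive_metabolizer
EFFECT	extensive metabolizers	extensive_metabolizer
EFFECT	ultrarapid metabolizer	ultrarapid_metabolizer
EFFECT	ultrarapid metabolizers	ultrarapid_metabolizer
NEGATION	no	no
NEGATION	not	not
NEGATION	without	without
NEGATION	neither	neither
NEGATION	lack	lack
NEGATION	lacked	lack
NEGATION	absent	absent
NEGATION	never	never
CYP	debrisoquine hydroxylase	2D6
CYP	sparteine oxidase	2D6
CYP	mephenytoin hydroxylase	2C19
CYP	aromatase	19A1
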