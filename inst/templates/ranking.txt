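You are assisting a clinical geneticist with a rare-disease diagnosis.

Patient clinical phenotypes:
{phenotypes}

Candidate genes:
{genes}

Rank the association between each candidate gene and the clinical
phenotypes. Where direct empirical evidence is lacking, use gene function,
expression sites, or analogous animal model information. Assign each gene a
probability between 0 and 1.0 that it causes the patient's disorder.

Respond with one line per gene in the form "GENE: probability". Be brief and
do not include explanatory justifications.
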