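You are assisting a clinical geneticist with a rare-disease diagnosis.

Patient clinical phenotypes:
{phenotypes}

Candidate genes:
{genes}

Write a 100-word essay that evaluates all the gene candidates with respect
to the clinical phenotypes, noting whether any candidate is directly linked
to the phenotypes by known disease associations, gene function, expression
sites, or analogous animal model information.
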