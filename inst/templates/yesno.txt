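You are assisting a clinical geneticist with a rare-disease diagnosis.

Patient clinical phenotypes:
{phenotypes}

Is disruption of the gene {gene} a plausible cause of these phenotypes?
Answer with exactly one word: Yes or No.
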