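Below is an essay evaluating candidate genes for a patient's phenotypes.

Essay:
{essay}

Based on the essay, is there at least one gene directly linked to the
phenotypes? Answer with exactly one word: Yes or No.
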