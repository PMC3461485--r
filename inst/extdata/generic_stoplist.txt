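# Generic clinical concepts too vague to be informative; the Novelty tier
# drops any predication whose subject or object matches one of these
# (case-insensitive). Extend for your own corpus.
pharmaceutical preparation
Pharmaceutical Preparations
patients
intervention regimes
Therapeutic procedure
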