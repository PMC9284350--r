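# First-person intake pattern rules (one Perl regex template per line).
# {DRUG} is replaced with the matched drug surface. Matching is done on
# lowercased text. These are an editable, transparent stand-in for human
# annotation of "did the poster actually take the drug"; no accuracy against
# human judgment is claimed.
\b(?:i am|i'm|i was|i have been|i've been|i had been|i'd been)\b[^.!?]{0,40}?\bon (?:a |an |the |my |some )?{DRUG}
\bi (?:take|took|taken|start(?:ed)?|stopp?ed|quit|use[d]?|tried)\b[^.!?]{0,40}?{DRUG}
\b(?:i'm|i am|i was|i've been|i have been) (?:still |just |now |back )?(?:taking|using)\b[^.!?]{0,40}?{DRUG}
\b(?:i've|i have|i was|i am|i'm) (?:been |being )?(?:prescribed|given)\b[^.!?]{0,40}?{DRUG}
\b(?:put|started|placed) me (?:back )?on (?:a |an |the |some )?{DRUG}
\bmy (?:daily |morning |evening )?{DRUG}\b
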