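# Pronunciation lexicon for syllable counting: word<TAB>syllables.
# Hand-curated exceptions where the vowel-group heuristic miscounts,
# mostly vowel hiatus (i-a, e-o, u-a) that the heuristic merges into one
# group. Looked up before the heuristic; lines starting with "#" ignored.
area	3
being	2
biology	4
business	2
cafeteria	5
chaos	2
create	2
creation	3
diagnosis	4
diarrhea	4
diet	2
dioxide	3
evaluate	4
evaluation	5
fluid	2
graduation	4
idea	3
immediately	5
influence	3
lion	2
liable	3
material	4
menstruation	4
mutual	3
nausea	3
neon	2
ovarian	4
period	3
poem	2
preliminary	5
quiet	2
radiation	4
radio	3
react	2
reaction	3
reality	4
ritual	3
science	2
situation	4
society	4
stereo	3
theater	3
trial	2
triage	3
usual	3
variable	4
video	3
violence	3
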