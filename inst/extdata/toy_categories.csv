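category,term
pronoun_i,i
pronoun_i,me
pronoun_i,my
pronoun_i,mine
pronoun_i,myself
social,friend
social,family
social,people
social,talk*
social,mom
social,dad
negemo,sad
negemo,angry
negemo,hurt*
negemo,afraid
negemo,cry*
negemo,hate
posemo,happy
posemo,good
posemo,love*
posemo,great
posemo,nice
health,ill*
health,sick
health,pain*
health,ache*
health,doctor
health,tired
cognitive,think*
cognitive,know
cognitive,because
cognitive,reason*
cognitive,wonder*
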