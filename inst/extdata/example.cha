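@Begin
@Languages:	pol
@Participants:	CHI Participant, EXA Investigator
@ID:	pol|example|CHI|||TD||participant|||
*EXA:	can you tell me the story as we go along ?
*CHI:	the frog [/] the frog flies .
*CHI:	&-um he is &=laughs happy .
*EXA:	I wonder what happens next .
*CHI:	<the frogs> [//] they fly over the town .
@End
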