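S1	Little interest or pleasure in doing things	interest
S2	Feeling down depressed or hopeless	feeling,depressed,hopeless
S3	Trouble falling or staying asleep or sleeping too much	sleep,asleep
S4	Feeling tired or having little energy	tired,energy
S5	Poor appetite or over eating	appetite,overeating
S6	Feeling bad about yourself or that you are a failure or have let yourself or your family down	failure,family
S7	Trouble concentrating on things such as reading the newspaper or watching television	concentration,reading,watching
S8	Moving or speaking so slowly that other people could have noticed or the opposite being restless that you have been moving around a lot more than usual	moving,speaking,restless
S9	Thoughts that you would be better off dead or of hurting yourself	dead,hurt,suicide
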