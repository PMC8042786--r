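contraction	expansion
can't	cannot
won't	will not
don't	do not
doesn't	does not
didn't	did not
isn't	is not
aren't	are not
wasn't	was not
weren't	were not
haven't	have not
hasn't	has not
hadn't	had not
couldn't	could not
shouldn't	should not
wouldn't	would not
mustn't	must not
i'm	i am
i've	i have
i'll	i will
i'd	i would
it's	it is
that's	that is
there's	there is
what's	what is
let's	let us
you're	you are
we're	we are
they're	they are
you've	you have
we've	we have
they've	they have
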