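word,role,valence
excellent,polar,1
wonderful,polar,0.9
love,polar,0.8
great,polar,0.75
happy,polar,0.75
enjoyed,polar,0.6
good,polar,0.5
fine,polar,0.4
useful,polar,0.4
interesting,polar,0.35
okay,polar,0.2
awful,polar,-1
terrible,polar,-0.9
hate,polar,-0.8
horrible,polar,-0.75
sad,polar,-0.75
failed,polar,-0.6
bad,polar,-0.5
frustrating,polar,-0.5
poor,polar,-0.4
boring,polar,-0.35
tired,polar,-0.3
not,negator,
never,negator,
no,negator,
cannot,negator,
didnt,negator,
wasnt,negator,
very,amplifier,
really,amplifier,
extremely,amplifier,
so,amplifier,
truly,amplifier,
barely,deamplifier,
slightly,deamplifier,
somewhat,deamplifier,
rather,deamplifier,
hardly,deamplifier,
but,adversative,
however,adversative,
although,adversative,
though,adversative,
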