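:)	2
:-)	2
:D	3
:-D	3
;)	1
;-)	1
:(	-2
:-(	-2
:'(	-3
D:	-2
:/	-1
:-/	-1
:|	-1
<3	3
</3	-3
:P	1
:-P	1
xD	3
=)	2
=(	-2
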