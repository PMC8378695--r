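grapheme	class
a	vowel
e	vowel
i	vowel
o	vowel
u	vowel
y	vowel
à	vowel
á	vowel
â	vowel
ä	vowel
æ	vowel
ã	vowel
å	vowel
ā	vowel
ą	vowel
è	vowel
é	vowel
ê	vowel
ë	vowel
ē	vowel
ė	vowel
ę	vowel
î	vowel
ï	vowel
í	vowel
ī	vowel
į	vowel
ì	vowel
ô	vowel
ö	vowel
ò	vowel
ó	vowel
œ	vowel
ø	vowel
ō	vowel
õ	vowel
û	vowel
ü	vowel
ù	vowel
ú	vowel
ū	vowel
ů	vowel
ÿ	vowel
ű	vowel
ő	vowel
ŵ	vowel
ŷ	vowel
ỳ	vowel
ẁ	vowel
ě	vowel
ý	vowel
ǫ	vowel
ŭ	approximant
w	approximant
ł	approximant
l	liquid
r	liquid
ř	liquid
m	nasal
n	nasal
ñ	nasal
ń	nasal
ŋ	nasal
ň	nasal
ß	fricative
z	fricative
v	fricative
s	fricative
f	fricative
ç	fricative
ć	fricative
ś	fricative
ŝ	fricative
ĉ	fricative
ĥ	fricative
h	fricative
ĵ	fricative
š	fricative
ž	fricative
ð	fricative
đ	fricative
x	affricate
j	affricate
ź	affricate
ż	affricate
ĝ	affricate
č	affricate
b	occlusive
c	occlusive
d	occlusive
g	occlusive
t	occlusive
k	occlusive
p	occlusive
q	occlusive
þ	occlusive
ď	occlusive
ť	occlusive
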