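family	category	genome
GH95	cellulose/pectin-active	CMU19
GH95	cellulose/pectin-active	CMU33
GH5	cellulose/pectin-active	CMU13
GH5	cellulose/pectin-active	CMU108
GH5	cellulose/pectin-active	CMU19
GH5	cellulose/pectin-active	CMU33
GH53	cellulose/pectin-active	CMU19
GH53	cellulose/pectin-active	CMU33
GH78	debranching	CMU13
GH78	debranching	CMU108
GH78	debranching	CMU19
GH78	debranching	CMU33
GH106	debranching	CMU13
GH106	debranching	CMU108
GH23	debranching	CMU13
GH2	oligosaccharide-degrading	CMU13
GH2	oligosaccharide-degrading	CMU108
GH43	oligosaccharide-degrading	CMU19
GH43	oligosaccharide-degrading	CMU33
GH92	oligosaccharide-degrading	CMU13
GH92	oligosaccharide-degrading	CMU108
GH92	oligosaccharide-degrading	CMU19
GH92	oligosaccharide-degrading	CMU33
GH3	oligosaccharide-degrading	CMU13
GH3	oligosaccharide-degrading	CMU108
GH3	oligosaccharide-degrading	CMU19
GH3	oligosaccharide-degrading	CMU33
GH105	oligosaccharide-degrading	CMU13
GH105	oligosaccharide-degrading	CMU108
GH105	oligosaccharide-degrading	CMU19
GH105	oligosaccharide-degrading	CMU33
GH18	oligosaccharide-degrading	CMU19
GH18	oligosaccharide-degrading	CMU33
GH130	oligosaccharide-degrading	CMU13
GH130	oligosaccharide-degrading	CMU108
GH35	oligosaccharide-degrading	CMU13
GH35	oligosaccharide-degrading	CMU108
GH35	oligosaccharide-degrading	CMU19
GH35	oligosaccharide-degrading	CMU33
GH32	oligosaccharide-degrading	CMU19
GH32	oligosaccharide-degrading	CMU33
GH38	oligosaccharide-degrading	CMU13
GH38	oligosaccharide-degrading	CMU108
GH127	oligosaccharide-degrading	CMU19
GH127	oligosaccharide-degrading	CMU33
GH42	oligosaccharide-degrading	CMU19
GH42	oligosaccharide-degrading	CMU33
GH147	oligosaccharide-degrading	CMU19
GH147	oligosaccharide-degrading	CMU33
PL22	polysaccharide lyases	CMU13
PL22	polysaccharide lyases	CMU108
PL22	polysaccharide lyases	CMU19
PL22	polysaccharide lyases	CMU33
CE6	carbohydrate esterases	CMU13
CE6	carbohydrate esterases	CMU108
CE6	carbohydrate esterases	CMU19
CE6	carbohydrate esterases	CMU33
CE12	carbohydrate esterases	CMU13
CE12	carbohydrate esterases	CMU108
CE4	carbohydrate esterases	CMU13
CE4	carbohydrate esterases	CMU108
CE4	carbohydrate esterases	CMU19
CE4	carbohydrate esterases	CMU33
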