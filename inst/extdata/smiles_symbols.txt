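B
C
N
O
P
S
F
I
H
K
c
n
o
s
p
Cl
Br
Si
Se
Na
Li
Mg
Al
Ca
Fe
Zn
Cu
Mn
Co
Ni
As
Sn
Te
Pt
Hg
Pb
Cr
Ti
Cd
Ag
Ba
0
1
2
3
4
5
6
7
8
9
%
-
=
#
:
/
\
.
(
)
+
@
@@
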