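# Wall image flows for squirmer far-field singularities.
# Machine-generated (symbolic differentiation of the Blake stokeslet image
# tensor with respect to the source position); do not edit by hand.
# Wall at y = 0, fluid in y > 0. Arguments: field point (x1,x2,x3), source
# location (Y1,Y2,Y3) with Y2 > 0, unit axis (e1,e2,e3). Unit strength:
# multiply by p (stresslet) or s (source dipole).
.stresslet_image_u <- function(x1, x2, x3, Y1, Y2, Y3, e1, e2, e3) {
  x0 <- Y2 + x2
  x4 <- x0^2
  x5 <- Y1 - x1
  x6 <- x5^2
  x7 <- Y3 - x3
  x8 <- x7^2
  x9 <- x6 + x8
  x10 <- x4 + x9
  x11 <- x10^(-7.0/2.0)
  x12 <- x0*x10
  x13 <- -x12
  x14 <- 5*Y2
  x15 <- x0*x14
  x16 <- 2*Y2
  x17 <- e2*x5
  x18 <- 3*x7
  x19 <- x17*x18*(x13 + x16*(x15 - 4*x4 + x9))
  x20 <- x10^2
  x21 <- 3*x10
  x22 <- x21*x6
  x23 <- 5*x6
  x24 <- Y2*x23 - x0*x23
  x25 <- Y2*x10
  x26 <- -x25
  x27 <- x12 + x26
  x28 <- x24 + x27
  x29 <- 6*Y2
  x30 <- e1*x7
  x31 <- 5*x8
  x32 <- Y2*x31 - x0*x31
  x33 <- x27 + x32
  x34 <- -x20
  x35 <- x21*x8
  x36 <- x34 + x35
  x37 <- x29*x33 + x36
  x38 <- e3*x5
  x39 <- 3*x12
  x40 <- -3*x25 + x39
  x41 <- x22 + x34
  x42 <- e1*x5
  x43 <- x28*x29 + x41
  x44 <- -x5
  x45 <- x44^2
  x46 <- -x7
  x47 <- x46^2
  x48 <- x45 + x47
  x49 <- x4 + x48
  x50 <- 3*x49
  x51 <- Y2*x0
  x52 <- 15*x51
  x53 <- x49^2
  x54 <- x4*x50
  x55 <- Y2*x49
  x56 <- x0*x55
  x57 <- x54 - 3*x56
  x58 <- -x53 + x57
  x59 <- x0*x20
  x60 <- -x59
  x61 <- x39*x6 + x60
  x62 <- 10*x2*x51
  x63 <- x0*x49
  x64 <- x46*x63
  x65 <- x21*x4
  x66 <- x0^3
  x67 <- 5*x66
  x68 <- x14*x4
  x69 <- -x67 + x68
  x70 <- x12*x29 + x20 + x29*(-2*x12 - x26 - x69) - x65
  x71 <- x16*x53
  x72 <- 3*x63
  x73 <- x44*x5
  x74 <- 6*x55
  x75 <- 5*x0
  x76 <- x55 - x63
  x77 <- 6*x4
  x78 <- x13 + x16*(-x15 + x48 + x77)
  x79 <- e3*x7
  x80 <- x20 - x29*(x27 + x69) + x65
  x81 <- 15*x4
  x82 <- x53 + x57
  x83 <- e2*x7
  x84 <- x46*x7
  x85 <- x39*x8 + x60
  x86 <- x0*x29
  x87 <- x29*(x55 + x67 - x68)
  x88 <- 6*x7
  c(x11*(e1*(-e2*(x16*(15*x4*x45 - x45*x50 - x45*x52 - x58) + x61) + e3*x43*x7 - x42*(-x29*(x24 + x40) - x41)) - e2*(e1*(6*Y2*x0*(x14*x73 - x73*x75 + x76) + 6*x0*x44*x49*x5 + x0*x53 - x45*x72 - x71 - x73*x74) + x17*x70 - 3*x38*(2*x0*x49*x7 - 2*x55*x7 - x62*x7 - x64)) + e3*(x19 + x30*(x20 + x22 + x28*x29) + x37*x38)), x11*(e1*(-e1*(x16*(x50*x73 - x52*x73 + x73*x81 + x82) + x61) + x17*x80 + 3*x5*x78*x79) - e2*(e1*(6*x4*x49*x5 + x44*x53 - x44*x54 + 2*x5*x53 - 6*x5*x56 - x5*x87) - e2*(-x16*x20 - x21*x66 + x25*x77 + x59 + x86*(-x40 - x69)) + e3*(6*x4*x49*x7 + x46*x53 - x46*x54 + 2*x53*x7 - x56*x88 - x7*x87)) + e3*(-e3*(x16*(x50*x84 - x52*x84 + x81*x84 + x82) + x85) + x18*x42*x78 + x80*x83)), x11*(e1*(x19 + x30*x43 + x38*(x20 + x29*x33 + x35)) - e2*(e3*(x0*x53 - x47*x72 + x64*x88 - x71 - x74*x84 + x86*(x14*x84 - x75*x84 + x76)) - 3*x30*(2*x0*x49*x5 - x44*x63 - 2*x5*x55 - x5*x62) + x70*x83) + e3*(e1*x37*x5 - e2*(x16*(15*x4*x47 - x47*x50 - x47*x52 - x58) + x85) - x79*(-x29*(x32 + x40) - x36))))
}

.sdipole_image_u <- function(x1, x2, x3, Y1, Y2, Y3, e1, e2, e3) {
  x0 <- Y1 - x1
  x4 <- x0^2
  x5 <- 7*Y2
  x6 <- Y2 + x2
  x7 <- 7*x6
  x8 <- x6^2
  x9 <- Y3 - x3
  x10 <- x9^2
  x11 <- x10 + x4 + x8
  x12 <- x11*x2
  x13 <- 3*x12
  x14 <- 10*Y2
  x15 <- x11^2
  x16 <- 3*x15
  x17 <- -x16
  x18 <- 5*x11
  x19 <- x18*x4
  x20 <- x17 + x19
  x21 <- x14*(x13 + x4*x5 - x4*x7) + x20
  x22 <- 3*x0
  x23 <- e3*x22
  x24 <- x23*x9
  x25 <- x10*x18
  x26 <- x17 + x25
  x27 <- x14*(x10*x5 - x10*x7 + x13) + x26
  x28 <- Y2*x6
  x29 <- x11*x28
  x30 <- x11*x8
  x31 <- x6^3
  x32 <- x9*(-x14*(x12 - 7*x31 + x5*x8) + x15 + 20*x29 - 25*x30)
  x33 <- x11^3
  x34 <- -x33
  x35 <- x0^4
  x36 <- 12*x15
  x37 <- 35*x35
  x38 <- x15*x2
  x39 <- 3*x38
  x40 <- 30*x11
  x41 <- Y2*x4
  x42 <- x4*x6
  x43 <- 6*Y2
  x44 <- Y2*x15
  x45 <- 15*x11
  x46 <- 20*x30
  x47 <- x6^4
  x48 <- 35*x47
  x49 <- 35*x31
  x50 <- Y2*x49
  x51 <- x28*x45
  x52 <- 2*Y2
  x53 <- Y2*x46 - x31*x45 + 5*x38 + x44 + x52*(x15 - x46 + x48 - x50 + x51)
  x54 <- e2*x22
  x55 <- 35*x8
  x56 <- x10*x55
  x57 <- 35*x10
  x58 <- x28*x57 - x56
  x59 <- x18*x8
  x60 <- -x18*x28 + x59
  x61 <- -x15 + x60
  x62 <- -x25*x6
  x63 <- x38 + x44
  x64 <- x62 + x63
  x65 <- x4*x55
  x66 <- Y2*x42
  x67 <- -x65 + 35*x66
  x68 <- -x51
  x69 <- x45*x8
  x70 <- x68 + x69
  x71 <- x67 + x70
  x72 <- -x19*x6
  x73 <- x39 + 3*x44
  x74 <- x72 + x73
  x75 <- x10*x16
  x76 <- x16*x4
  x77 <- x33 + x76
  x78 <- Y2*x19 + x38 + x72
  x79 <- Y2*x25 + x62
  x80 <- -x10*x4*x45 + x43*(-x41*x57 + x42*x57 + x78 + x79)
  x81 <- Y2*x59 - x18*x31
  x82 <- x43*(-Y2*x65 + x4*x49 + x78 + x81)
  x83 <- 75*x30
  x84 <- x15*x8
  x85 <- x44*x6
  x86 <- 9*x84 - 12*x85
  x87 <- (1.0/2.0)/x11^(9.0/2.0)
  x88 <- x11*x31
  x89 <- 20*Y2*x11*x8 + 3*x15*x2 - x44 - x52*(x15 + 10*x30 - x48 + x50 + x68) - 25*x88
  x90 <- e1*x22
  x91 <- 3*x9
  x92 <- e3*x91
  x93 <- x15 + x60
  x94 <- -x25 + x58
  x95 <- -x19
  x96 <- x63 + x72
  x97 <- x62 + x73
  x98 <- -x16*x8 + x34
  x99 <- x43*(-Y2*x56 + x10*x49 + x38 + x79 + x81) + x75
  x100 <- x9*x90
  x101 <- x9^4
  x102 <- 35*x101
  x103 <- x10*x40
  x104 <- e2*x91
  c(x87*(-e1*(-x75 + x77 + x80) + e1*(15*x11*x35 - x34 - x36*x4 - x43*(-Y2*x37 + x37*x6 + x39 + x40*x41 - x40*x42)) - e1*(60*x11*x66 - x4*x83 + x77 + x82 + x86) + x21*x24 - x23*x32 + x24*x27 - x53*x54 + x54*(x52*(x20 + x71) + x74) + x54*(x52*(x25 + x58 + x61) + x64)), x87*(-e2*(-x10*x69 - x98 - x99) + e2*(x4*x69 + x76 + x82 + x98) + e2*(60*Y2*x88 - 45*x11*x47 + x33 + x43*(30*Y2*x30 - Y2*x48 + x39 + 35*x6^5 - 30*x88) + 24*x84 - 36*x85) + x89*x90 + x89*x92 + x90*(-x52*(x93 + x94) + x64) + x90*(-x52*(x16 + x71 + x95) + x74) + x92*(-x52*(x16 + x70 + x94) + x97) + x92*(-x52*(x67 + x93 + x95) + x96)), x87*(-e3*(x33 + x75 - x76 + x80) + e3*(-x10*x36 + 15*x101*x11 - x34 - x43*(-Y2*x102 + Y2*x103 + x102*x6 - x103*x6 + x39)) - e3*(60*x10*x29 - x10*x83 + x33 + x86 + x99) + x100*x21 + x100*x27 - x104*x53 + x104*(x52*(x19 + x61 + x67) + x96) + x104*(x52*(x26 + x58 + x70) + x97) - x32*x90))
}

.stresslet_image_curl <- function(x1, x2, x3, Y1, Y2, Y3, e1, e2, e3) {
  x0 <- Y2 + x2
  x4 <- x0^2
  x5 <- Y1 - x1
  x6 <- x5^2
  x7 <- Y3 - x3
  x8 <- x7^2
  x9 <- x4 + x6 + x8
  x10 <- x9^(-9.0/2.0)
  x11 <- x0*x9
  x12 <- Y2*x9
  x13 <- x0^3
  x14 <- 7*x13
  x15 <- 7*Y2
  x16 <- x15*x4
  x17 <- -x14 + x16
  x18 <- -x12 + x17
  x19 <- 10*Y2
  x20 <- x9^2
  x21 <- 5*x4
  x22 <- x21*x9
  x23 <- x20 + x22
  x24 <- x5*x7
  x25 <- e2*x24
  x26 <- x25*(-x19*(x11 + x18) + x23)
  x27 <- 5*x9
  x28 <- x27*x8
  x29 <- -x28
  x30 <- 35*x4
  x31 <- x30*x8
  x32 <- 5*x11
  x33 <- -Y2*x32
  x34 <- x0*x8
  x35 <- 35*Y2
  x36 <- -x31 + x33 + x34*x35
  x37 <- 2*Y2
  x38 <- x0*x20
  x39 <- -x38
  x40 <- x32*x8
  x41 <- x39 + x40
  x42 <- e3*x5
  x43 <- -x5
  x44 <- x43*x5
  x45 <- x30*x44
  x46 <- x0*x35
  x47 <- x44*x46
  x48 <- x43^2
  x49 <- -x7
  x50 <- x49^2
  x51 <- x4 + x48 + x50
  x52 <- x21*x51
  x53 <- Y2*x51
  x54 <- 5*x53
  x55 <- x0*x54
  x56 <- -x55
  x57 <- x52 + x56
  x58 <- x51^2
  x59 <- 5*x51
  x60 <- x44*x59 + x58
  x61 <- x45 - x47 + x57 + x60
  x62 <- x32*x6
  x63 <- x39 + x62
  x64 <- e1*x7
  x65 <- 3*e1
  x66 <- x0*x51
  x67 <- -x53
  x68 <- x17 + x67
  x69 <- x52 - x58
  x70 <- x25*(-x19*(-3*x66 - x68) - x69)
  x71 <- -x52 + x55
  x72 <- -x45 + x47 + x60 + x71
  x73 <- x37*x72
  x74 <- x0*x58
  x75 <- 5*x66
  x76 <- x50*x75
  x77 <- x49*x7
  x78 <- x30*x77
  x79 <- x46*x77
  x80 <- x58 + x59*x77
  x81 <- x71 - x78 + x79 + x80
  x82 <- -3*Y2*x9 + 3*x11
  x83 <- x0*x19
  x84 <- 5*x13
  x85 <- Y2*x20
  x86 <- 10*x12*x4 - x84*x9 - 2*x85
  x87 <- x38 + x83*(-x17 - x82) + x86
  x88 <- 3*e2
  x89 <- x7*x88
  x90 <- x43*x58
  x91 <- -x90
  x92 <- x5*x53
  x93 <- 10*x0
  x94 <- x92*x93
  x95 <- x43*x52
  x96 <- x19*(x14 - x16 + x53)
  x97 <- x65*x7
  x98 <- x4*x51
  x99 <- 15*x98
  x100 <- x77*x99
  x101 <- Y2*x58
  x102 <- x51*x84
  x103 <- x21*x53
  x104 <- x101 + x102 - x103
  x105 <- 6*Y2
  x106 <- x51^3
  x107 <- x4*x58
  x108 <- -6*Y2*x0*x58 + x106 + 9*x107
  x109 <- 3*x20
  x110 <- x11*x19
  x111 <- 2*x66
  x112 <- -x109 - x110 - x19*(-x111 - x68) + 15*x4*x9
  x113 <- x5*x97
  x114 <- 35*x13
  x115 <- 2*x58
  x116 <- x0*x53
  x117 <- -x37*(-Y2*x114 + 35*x0^4 + x115 + 15*x116 - 25*x98) - 3*x38 - x86
  x118 <- x66*x7
  x119 <- 10*x49
  x120 <- x118*x119
  x121 <- 2*x74
  x122 <- x53*x7
  x123 <- 5*x49
  x124 <- x122*x123
  x125 <- -x101 - x102 + x103
  x126 <- Y2*x78 - x114*x77 - x124 + x125
  x127 <- 3*x58
  x128 <- x127*x50
  x129 <- x49*x58
  x130 <- x129*x7
  x131 <- 15*x50
  x132 <- 30*x98
  x133 <- 30*x0
  x134 <- 3*x107
  x135 <- 6*x0*x101 + x106 - x134
  x136 <- -x20 + x22
  x137 <- x109*x8
  x138 <- x30*x50
  x139 <- 3*x74
  x140 <- -x139
  x141 <- x104 + x140
  x142 <- 15*x9
  x143 <- x142*x4
  x144 <- x9^3
  x145 <- x109*x4 - x144
  x146 <- x32*x7^3
  x147 <- x50*x7
  x148 <- x58*x7
  x149 <- 5*x0
  x150 <- 10*x98
  x151 <- x50*x59
  x152 <- 3*e3
  x153 <- x118*x123
  x154 <- x57 + x78 - x79 + x80
  x155 <- x49*x8
  x156 <- -x129
  x157 <- 2*x148
  x158 <- x122*x93
  x159 <- x49*x52
  x160 <- x153 + x74
  x161 <- x106 + 3*x130
  x162 <- x25*(x110 + x19*(-2*x11 - x18) + x20 - x22)
  x163 <- 2*x101
  x164 <- -x163
  x165 <- x5*x66
  x166 <- 5*x43
  x167 <- x165*x166
  x168 <- 7*x0
  x169 <- x15*x6 - x168*x6
  x170 <- x66 + x67
  x171 <- x53 - x66
  x172 <- 10*x8
  x173 <- -x153
  x174 <- x15*x8 - x168*x8
  x175 <- -x74
  x176 <- x48*x75
  x177 <- 10*x43
  x178 <- x152*x24
  x179 <- x37*x81
  x180 <- x44*x77
  x181 <- x166*x92
  x182 <- -x105*(-35*x0*x180 + x101 + x124 - x167 + x173 + x175 + x180*x35 + x181)
  x183 <- x127*x48
  x184 <- 15*x48
  x185 <- x27*x6
  x186 <- -x185
  x187 <- x167 + x74
  x188 <- x5*x90
  x189 <- x106 + 3*x188
  x190 <- x48*x59
  x191 <- x56 + x69
  x192 <- x115*x5
  x193 <- x48*x5
  x194 <- 2*x53
  x195 <- x109*x6
  x196 <- x6*x8
  x197 <- 5*x12
  x198 <- x105*(x196*x35 - x197*x6 - x197*x8 - 35*x34*x6 + x41 + x62 + x85) - x137 + x142*x196 + x144 - x195
  x199 <- x5*x88
  x200 <- x152*x5
  x201 <- x30*x6
  x202 <- -x201 + x33 + x46*x6
  x203 <- x44*x99
  x204 <- Y2*x45 - x114*x44 + x125 - x181
  x205 <- x30*x48
  x206 <- x32*x5^3
  x207 <- x43*x6
  c(x10*(e2*(e3*(-x100 - x105*(-Y2*x31 + 5*Y2*x51*x8 - x104 + 35*x13*x8) - x108 - 30*x34*x53 + 30*x4*x51*x8 + 3*x49*x58*x7 + 6*x58*x8) - x87*x89 + x97*(10*x4*x5*x51 + 2*x5*x58 - x5*x96 - x91 - x94 - x95)) - e2*(e3*(-x105*(x120 + x121 + x126) + x122*x133*x49 - x128 + 6*x130 + x131*x98 - x132*x77 + x135) + x112*x113 + x117*x89) + e3*(e2*(x100 - x105*(x126 + x160) + x134 + x161) - x152*(3*x0*x20*x7 - x146 - x37*(x150*x7 - x155*x46 + x155*x59 + x156 + x157 - x158 - x159 + x31*x49 + x49*x55)) + x65*(x0*x90 + x153*x43 + x154*x37*x5)) + e3*(3*e1*x5*(-x37*(x136 + x28 + x36) - x41) - e2*(x105*(Y2*x138 - x114*x50 + x131*x66 + x141 - x50*x54) + x137 - x143*x8 + x145) - x152*(x146 + x37*(x116*x119 - x122*x149 + 2*x129 - x138*x7 + x147*x46 - x148 - x150*x49 + x151*x7 + x52*x7) - x38*x7)) - x65*(x26 + x42*(-x37*(x23 + x29 + x36) - x41) - x64*(x37*x61 + x63)) - x65*(x42*(-x37*x81 + x74 + x76) + x64*(-x38 + x62 - x73) + x70)), -x10*(-e1*(e3*x198 + x89*(-x37*(-x190 - x191 + 35*x4*x48 - x46*x48) - x63) - x97*(-x19*(-x111*x43 + x15*x193 + x165 - x168*x193 + x194*x43 - x92) + x192 + x43^3*x59 + x90)) + e1*(3*e2*x7*(x187 - x73) - e3*(x128 + x131*x44*x51 + x182 + x189) - x113*(x109 + x186 + x19*(-x169 - x82))) + 3*e2*(e1*x7*(10*Y2*x0*(x169 + x170) + 10*x0*x51*x6 - x139 - x164 - x167 - 10*x53*x6) - x162 - x42*(-x119*x122 + x120 + x164 + x74 - x76 + x83*(x15*x77 - x168*x77 + x171))) + e3*(e1*x198 + x199*(-x37*(-x151 - x191 + 35*x4*x50 - x46*x50) - x41) - x200*(x129 + x157 - x19*(-x111*x49 + x118 - x122 + x147*x15 - x147*x168 + x194*x49) + x49^3*x59)) - e3*(-e1*(x161 + x182 + x183 + x184*x51*x77) + 3*e2*x5*(x160 - x179) - x178*(x109 + x19*(-x174 - x82) + x29)) - x88*(e3*x5*(x140 + x163 - x172*x53 + x172*x66 + x173 + x83*(x170 + x174)) - x162 - x64*(10*Y2*x0*(x15*x44 - x168*x44 + x171) + 10*x0*x43*x5*x51 - x163 - x175 - x176 - x177*x92))), x10*(-e1*(e2*(-x105*(x187 + x204) + x134 + x189 + x203) + x152*(x123*x165*x43 + x37*x61*x7 + x49*x74) - x65*(3*x0*x20*x5 - x206 - x37*(x150*x5 + x192 + x201*x43 - x207*x46 + x207*x59 + x43*x55 + x91 - x94 - x95))) - e1*(-e2*(x105*(Y2*x205 - x114*x48 + x141 + x184*x66 - x48*x54) - x143*x6 + x145 + x195) + 3*e3*x7*(-x37*(x136 + x185 + x202) - x63) - x65*(x206 + x37*(x116*x177 - x149*x92 - x150*x43 + x190*x5 + x193*x46 - x205*x5 + x5*x52 - x5*x58 + 2*x90) - x38*x5)) + e2*(e1*(-x105*(x121 + x165*x177 + x204) - x132*x44 + x133*x43*x92 + x135 - x183 + x184*x98 + 6*x188) + x112*x178 + x117*x199) - e2*(e1*(-x105*(-Y2*x201 + 5*Y2*x51*x6 - x104 + 35*x13*x6) - x108 - 30*x116*x6 - x203 + 30*x4*x51*x6 + 3*x43*x5*x58 + 6*x58*x6) - x199*x87 + x200*(-x156 - x158 - x159 + 10*x4*x51*x7 + 2*x58*x7 - x7*x96)) + 3*e3*(x26 - x42*(x154*x37 + x41) + x64*(-x37*(x186 + x202 + x23) - x63)) + 3*e3*(x42*(-x179 - x38 + x40) + x64*(x176 - x37*x72 + x74) + x70)))
}

.sdipole_image_curl <- function(x1, x2, x3, Y1, Y2, Y3, e1, e2, e3) {
  x0 <- Y2 + x2
  x4 <- x0^2
  x5 <- Y1 - x1
  x6 <- x5^2
  x7 <- Y3 - x3
  x8 <- x7^2
  x9 <- x4 + x6 + x8
  x10 <- x2*x9
  x11 <- 3*x10
  x12 <- x0*x6
  x13 <- Y2*x6
  x14 <- -7*x12 + 7*x13
  x15 <- x11 + x14
  x16 <- 10*Y2
  x17 <- x9^2
  x18 <- 3*x17
  x19 <- -x18
  x20 <- x6*x9
  x21 <- 5*x20
  x22 <- x19 + x21
  x23 <- x15*x16 + x22
  x24 <- 2*e1
  x25 <- x24*x7
  x26 <- x25*x5
  x27 <- x0*x26
  x28 <- x0*x8
  x29 <- Y2*x8
  x30 <- -7*x28 + 7*x29
  x31 <- x11 + x30
  x32 <- x8*x9
  x33 <- 5*x32
  x34 <- x19 + x33
  x35 <- x16*x31 + x34
  x36 <- x0*x9
  x37 <- Y2*x36
  x38 <- x4*x9
  x39 <- x0^3
  x40 <- 7*x39
  x41 <- Y2*x4
  x42 <- -x40 + 7*x41
  x43 <- x10 + x42
  x44 <- -x16*x43 + x17 + 20*x37 - 25*x38
  x45 <- 14*x41
  x46 <- Y2*x9
  x47 <- -3*x46
  x48 <- 2*Y2
  x49 <- 5*x38
  x50 <- 4*x37 - x49
  x51 <- x48*(-2*x36 + 14*x39 - x45 - x47) + x50
  x52 <- 10*x28
  x53 <- e1*x5
  x54 <- 10*x53
  x55 <- x54*x7
  x56 <- x0*x51
  x57 <- x0*x20
  x58 <- -x57
  x59 <- x37 - x38
  x60 <- 14*x4
  x61 <- x6*x60
  x62 <- 14*x0
  x63 <- x13*x62
  x64 <- x20 + x61 - x63
  x65 <- 10*x8
  x66 <- e3*x65
  x67 <- 3*x37
  x68 <- -3*x4*x9 + x67
  x69 <- x15*x48
  x70 <- -x61 + x63
  x71 <- Y2*(-x19 - 7*x20 - x70) - x0*x69 - x57
  x72 <- x0*x32
  x73 <- x31*x48
  x74 <- x60*x8
  x75 <- x29*x62
  x76 <- -x74 + x75
  x77 <- Y2*(-x19 - 7*x32 - x76) - x0*x73 - x72
  x78 <- Y2*x17
  x79 <- x17*x2
  x80 <- x39*x9
  x81 <- 20*x38
  x82 <- Y2*x81
  x83 <- x0^4
  x84 <- 35*x83
  x85 <- 35*Y2*x39
  x86 <- 15*x37
  x87 <- x48*(x17 - x81 + x84 - x85 + x86) + x78 + 5*x79 - 15*x80 + x82
  x88 <- e2*x7
  x89 <- 2*x88
  x90 <- x0*x89
  x91 <- 3*x79
  x92 <- -x86
  x93 <- 10*x38
  x94 <- x48*(-x17 + 35*x83 - x85 - x92 - x93) - x78 - 25*x80 + x82 + x91
  x95 <- 2*e3
  x96 <- x8*x95
  x97 <- e3*x9
  x98 <- -5*x37 + x49
  x99 <- x17 + x98
  x100 <- 35*x6
  x101 <- 35*x0
  x102 <- -x100*x4 + x101*x13
  x103 <- x102 - x21
  x104 <- -x0*x21
  x105 <- x78 + x79
  x106 <- x104 + x105
  x107 <- -2*Y2*(x103 + x99) + x106
  x108 <- 35*x8
  x109 <- x101*x29 - x108*x4
  x110 <- x109 - x33
  x111 <- -x0*x33
  x112 <- x105 + x111
  x113 <- -2*Y2*(x110 + x99) + x112
  x114 <- -x17
  x115 <- x114 + x98
  x116 <- x106 + x48*(x102 + x115 + x21)
  x117 <- 15*x38 + x92
  x118 <- x117 + x18
  x119 <- 3*x78
  x120 <- x119 + x91
  x121 <- x111 + x120
  x122 <- x121 - x48*(x110 + x118)
  x123 <- x109 + x117 + x34
  x124 <- x121 + x123*x48
  x125 <- x104 + x120
  x126 <- x125 - x48*(x103 + x118)
  x127 <- x0*x17
  x128 <- -5*x80
  x129 <- Y2*x38
  x130 <- x43*x48
  x131 <- 14*x39
  x132 <- Y2*(-Y2*x131 + x17 + 14*x37 - 21*x38 + 14*x83) - x0*x130 + 5*x127 + x128 + 4*x129 - 2*x78
  x133 <- x9^3
  x134 <- -x133
  x135 <- 8*x80
  x136 <- x17*x4
  x137 <- 9*x136
  x138 <- x0^5
  x139 <- 40*Y2*x0*x17 - 5*Y2*x135 - 5*x134 - 5*x137 - 5*x48*(27*Y2*x4*x9 - 28*Y2*x83 + 8*x0*x17 - x119 + 28*x138 - 36*x80) + 30*x83*x9
  x140 <- x7^3
  x141 <- x37*x7
  x142 <- x140*x9
  x143 <- -x7
  x144 <- x143*x17
  x145 <- 14*Y2
  x146 <- x0*x145
  x147 <- 7*x38
  x148 <- 7*x37
  x149 <- -x140*x146 + x140*x60 + x142 + x143*x147 - x143*x148 + x144
  x150 <- e3*x7
  x151 <- 10*x150
  x152 <- x83*x9
  x153 <- x0*x78
  x154 <- Y2*x80
  x155 <- 3*x36 + x47
  x156 <- -Y2*x84 + 30*x129 + 35*x138 - 30*x80 + x91
  x157 <- -Y2*x156 - 4*x136 + 15*x152 + 6*x153 - 20*x154 + x16*x4*(x155 + x42)
  x158 <- -2*Y2*x4*x9 - 2*x0*x17 + x78 + 2*x80
  x159 <- 28*x39
  x160 <- Y2*x20
  x161 <- 28*x4
  x162 <- x13*x161 - x159*x6 - 7*x160 + 16*x57
  x163 <- x20*x4
  x164 <- 10*x163
  x165 <- x17*x6
  x166 <- 5*x165
  x167 <- x133 - x166
  x168 <- x164 + x167
  x169 <- 3*x133
  x170 <- -x169
  x171 <- x17*x8
  x172 <- 5*x171
  x173 <- x8*x93
  x174 <- -x173
  x175 <- Y2*x32
  x176 <- 7*x175
  x177 <- -x159*x8 + x161*x29 - x176 + 16*x72
  x178 <- 6*Y2
  x179 <- x119 - 6*x127 - x178*x38 + 6*x80
  x180 <- x7^4
  x181 <- 10*x36
  x182 <- -35*Y2*x180 - 30*x0*x8*x9 + x101*x180 + 30*x175 + x91
  x183 <- -x182
  x184 <- x0*x48
  x185 <- 140*Y2*x0
  x186 <- x180*x9
  x187 <- x38*x8
  x188 <- -x129 + x80
  x189 <- Y2*x49 + x128 + x79
  x190 <- Y2*x21 + x104
  x191 <- x100*x39 - 35*x13*x4 + x189 + x190
  x192 <- x191*x48
  x193 <- -x16*(x13*x60 - x131*x6 - x160 + x188 + x57) + x165 + x192
  x194 <- -x175 + x72
  x195 <- -x131*x8 + x194 + x29*x60
  x196 <- -x127 + x78
  x197 <- 6*x136
  x198 <- Y2*x33 + x111
  x199 <- -35*Y2*x4*x8 + x108*x39 + x189 + x198
  x200 <- x199*x48
  x201 <- x171 + x200
  x202 <- 3*x53
  x203 <- x202*x7
  x204 <- x203*x35
  x205 <- x133 - 12*x17*x8 + x178*x183 + 15*x186
  x206 <- 3*x88
  x207 <- x0*x171
  x208 <- -x172
  x209 <- x173 + x208
  x210 <- x108*x12 - x108*x13 + x190 + x198 + x79
  x211 <- x210*x48
  x212 <- Y2*(10*Y2*x0*x6*x9 + 10*Y2*x0*x8*x9 - x108*x20 - 140*x13*x28 - x168 - x209 + 140*x4*x6*x8) + x0*x211 - x20*x52
  x213 <- x18*x6
  x214 <- 15*x20
  x215 <- x178*x210 - x214*x8
  x216 <- x18*x8
  x217 <- x133 + x216
  x218 <- -e3*(-x213 + x215 + x217) + x116*x206 + x203*x23
  x219 <- 3*x150
  x220 <- e2*(x133 + 24*x136 - 45*x152 - 36*x153 + 60*x154 + x156*x178) + x202*x94 + x219*x94
  x221 <- 140*x39
  x222 <- -10*Y2*x39*x9 + 10*x152 + 10*x153 - 15*x17*x4
  x223 <- -x0*x169 + x133*x48 + x18*x39 - 4*x4*x78
  x224 <- Y2*x72
  x225 <- x137 - 12*x153
  x226 <- e3*(x178*x199 - 75*x187 + x217 + 60*x224 + x225) + x203*x44 + x206*x87
  x227 <- x18*x4
  x228 <- x178*x191 + x213
  x229 <- e2*(x134 + x214*x4 - x227 + x228) + x107*x219 + x126*x202
  x230 <- -x199
  x231 <- x133 - x216
  x232 <- e2*(-x178*x230 - x227 - x231 + 15*x4*x8*x9) + x113*x202 + x122*x219
  x233 <- (3.0/2.0)/x9^(11.0/2.0)
  x234 <- 14*x2
  x235 <- x32 + x73
  x236 <- 10*x6
  x237 <- e1*x236*x7
  x238 <- x20 + x69
  x239 <- x25*x6
  x240 <- -x130 + x2*x45 + x50
  x241 <- x5*x97
  x242 <- 3*x38 - x67
  x243 <- x20 + x70
  x244 <- 10*x5*x88
  x245 <- -x72
  x246 <- x32 + x76
  x247 <- x36 - x46
  x248 <- x114 - 8*x37 + 8*x38
  x249 <- x5*x89
  x250 <- x112 + x48*(x109 + x115 + x33)
  x251 <- x102 + x117 + x22
  x252 <- x125 + x251*x48
  x253 <- x5^4
  x254 <- x253*x9
  x255 <- -35*Y2*x253 - 30*x0*x6*x9 + x101*x253 + 30*x160 + x91
  x256 <- x16*(x188 + x195)
  x257 <- -4*x153 + x227
  x258 <- Y2*x57
  x259 <- -x171
  x260 <- 14*x8
  x261 <- x219*x5
  x262 <- x23*x261
  x263 <- -x255
  x264 <- x133 - 12*x165 + x178*x263 + 15*x254
  x265 <- e2*x5
  x266 <- 3*x265
  x267 <- x133*x5
  x268 <- x5^3
  x269 <- 14*x268
  x270 <- -x5
  x271 <- 7*x270
  x272 <- x127*x270 + x268*x36
  x273 <- -x268*x46 - x270*x78 + x272
  x274 <- x213 + x215 + x231
  x275 <- x250*x266 + x261*x35
  x276 <- e1*(x133 - 75*x163 + x225 + x228 + 60*x258) + x261*x44 + x266*x87
  x277 <- x5*x7*x95
  x278 <- x0*x277
  x279 <- x32 + x74 - x75
  x280 <- x24*x6
  x281 <- 2*e2
  x282 <- x0*x281*x5
  x283 <- -x146*x268 + x147*x270 - x148*x270 + x17*x270 + x268*x60 + x268*x9
  x284 <- x0*x165
  c(-x233*(e3*x51*x52 + x0*x218 - x0*x226 + x0*(e3*x205 + x204 + x206*(x121 + x123*x48)) + x107*x96 - x107*x97 + x113*x26 + x116*x90 + x122*x96 - x122*x97 + x124*x90 + x126*x26 - x132*x55 + x139*x88 - x151*(x0*x142 + x0*x144 + x48*(-3*x141 - x149 + 3*x4*x7*x9)) - 4*x157*x88 + x220*x7 + x229*x7 + x23*x27 + x232*x7 + x26*x94 + x27*x35 - x27*x44 - x54*(x0*x140*x9 - x127*x7 - x48*(x141 + x149 - x38*x7)) + x55*x56 - x55*x71 - x55*x77 - x55*(x48*(-x64 - x68) + x57) - x66*(-x48*(x59 + x64) - x58) - x87*x90 - x88*(x16*(-x158 - x162) + x168) + x88*(x16*(x177 + x179) + x170 + x172 + x174) + x89*(-x136 + x164 + x193) + x89*(x134 - x16*(-8*x129 + x135 + x195 + x196) + x173 - x197 + x201) + x94*x96 - x94*x97 + x95*(x0*x17*x6 - x207 - x212) - x95*(Y2*(60*Y2*x0*x8*x9 - x169 + 30*x17*x8 - x180*x185 + 140*x180*x4 - 35*x186 - 60*x187) + 4*x0*x17*x8 - x180*x181 - x183*x184) + x95*(10*Y2*x17*x8 - Y2*(80*Y2*x0*x8*x9 - x133 - 115*x187 - x208 - x221*x29 - x222 + 140*x8*x83) - x0*x200 - 26*x207 - x223 - 40*x29*x38 + 50*x39*x8*x9)), x233*(e1*x23*x7*x9 + 10*e1*x240*x6*x7 + e1*x35*x7*x9 + 2*e1*x44*x6*x7 - e1*x44*x7*x9 + 2*e1*x7*(-x193 - x257 - 40*x258 + 50*x4*x6*x9) + 4*e1*x7*(-Y2*x255 + 10*x13*(x14 + x155) - 2*x165 + 5*x254) + 2*e2*x250*x5*x7 + 2*e2*x252*x5*x7 + 10*e2*x5*x7*(-x245 - x48*(x242 + x246)) + 10*e2*x5*x7*(-x127 - x48*(x243 + x248) - x58) + 2*e3*x23*x5*x8 + 2*e3*x35*x5*x8 + e3*x44*x5*x9 + 10*e3*x5*x8*(-x13*x234 + x238) + 10*e3*x5*x8*(x114 + x145*(x247 - x28 + x29) + x235) - 4*e3*x5*(-Y2*x182 - 2*x171 + 5*x186 + 10*x29*(x155 + x30)) + 2*e3*x5*(-50*x187 + x201 + 40*x224 - x256 + x257) - x116*x249 - x124*x249 - x218*x5 + x226*x5 - x23*x239 - x23*x241 - x237*(-x234*x29 + x235) - x237*(x114 + x145*(-x12 + x13 + x247) + x238) - x239*x35 - x240*x5*x66 - x241*x35 - x244*(-x48*(x242 + x243) - x58) - x244*(-x127 - x245 - x48*(x246 + x248)) - x25*(x133 - x16*(-x12*x260 + x13*x260 - 8*x160 + x194 + x196 + 8*x57) + 6*x165 - x20*x65 + x211 + x259) - x276*x7 - x44*x5*x96 - x5*(e3*x205 + x124*x206 + x204) + x7*(-e1*x274 + x275) + x7*(e1*x264 + x252*x266 + x262) - x95*(10*Y2*(-x175*x5 + x176*x270 - x269*x28 + x269*x29 - x271*x72 + x273 + x5*x72) + x17*x268 - 6*x171*x5 - x211*x5 - x267 + 10*x268*x8*x9)), -x233*(e1*x113*x9 - 10*e1*x12*x51 + e1*x126*x9 + 10*e1*x5*(x272 + x48*(-x283 + 3*x4*x5*x9 - x5*x67)) + 10*e1*x6*(-x245 - x48*(x279 + x59)) + e1*x9*x94 + 2*e1*(-x207 + x212 + x284) + 2*e1*(Y2*(60*Y2*x0*x6*x9 - 60*x163 - x169 + 30*x17*x6 - x185*x253 + 140*x253*x4 - 35*x254) + 4*x0*x17*x6 - x181*x253 - x184*x263) + 2*e1*(Y2*(80*Y2*x0*x6*x9 - x13*x221 - 115*x163 - x167 - x222 + 140*x6*x83) + x184*x191 - 50*x20*x39 + 40*x20*x41 + x223 - x236*x78 + 26*x284) + 2*e2*x0*x5*x87 + 4*e2*x157*x5 + e2*x5*(x133 + x16*(-x158 - x177) + x209) + 2*e2*x5*(x136 + x174 + x230*x48 + x256 + x259) + 2*e3*x0*x44*x5*x7 + 10*e3*x132*x5*x7 + 10*e3*x5*x7*x71 + 10*e3*x5*x7*x77 + 10*e3*x5*x7*(x48*(-x279 - x68) + x72) + 10*e3*x7*(x0*x268*x9 - x127*x5 - x48*(x283 + x37*x5 - x38*x5)) + x0*x276 - x0*(-e1*x274 + x275) - x0*(e1*x264 + x262 + x266*(x125 + x251*x48)) - x107*x277 - x113*x280 - x122*x277 - x126*x280 - x139*x265 - x151*x5*x56 - x220*x5 - x229*x5 - x23*x278 - x232*x5 - x250*x282 - x252*x282 - x265*(x16*(x162 + x179) - x164 + x166 + x170) - x277*x94 - x278*x35 - x280*x94 - x281*(-x16*(x129*x271 - x129*x5 - x131*x268 + x268*x45 - x270*x40*x9 + x273 + x5*x80) + x17*x268 + x192*x5 - x197*x5 - x267 + x268*x93)))
}

.stresslet_free_curl <- function(x1, x2, x3, Y1, Y2, Y3, e1, e2, e3) {
  x0 <- Y2 - x2
  x4 <- x0^2
  x5 <- Y1 - x1
  x6 <- x5^2
  x7 <- Y3 - x3
  x8 <- x7^2
  x9 <- x6 + x8
  x10 <- x4 + x9
  x11 <- x10^(-7.0/2.0)
  x12 <- x4 + x6
  x13 <- e3*x0
  x14 <- x13*x5
  x15 <- e1*x7
  x16 <- x0*x15
  x17 <- -e1*x0*x10*x7 + 5*x16*x6
  x18 <- e2*x7
  x19 <- x18*x5
  x20 <- -e2*x10*x5*x7 + 5*x19*x4
  x21 <- -x14*(x12 + 6*x8) - x17 - x20
  x22 <- 3*e1
  x23 <- -e3*x0*x10*x5 + 5*x14*x8
  x24 <- x17 + x19*(6*x4 + x9) + x23
  x25 <- x10^2
  x26 <- e2*x25
  x27 <- 15*x8
  x28 <- x27*x4
  x29 <- 3*x10
  x30 <- x29*x8
  x31 <- x29*x4
  x32 <- x0*x7
  x33 <- 3*e3
  x34 <- x33*(x12 - 4*x8)
  x35 <- e1*x0
  x36 <- x35*x5
  x37 <- -x27*x36 + x29*x36
  x38 <- -4*x4 + x9
  x39 <- 3*e2
  x40 <- 15*x4
  x41 <- x15*x5
  x42 <- x29*x41 - x40*x41
  x43 <- -e3*x25 + e3*x30
  x44 <- -x30
  x45 <- -x25
  x46 <- x28 + x45
  x47 <- 15*x0^3
  x48 <- -x31
  x49 <- 15*x7^3
  x50 <- 9*x7
  x51 <- x4 + x8
  x52 <- x16*(x51 + 6*x6) + x20 + x23
  x53 <- e1*x25
  x54 <- x27*x6
  x55 <- x29*x6
  x56 <- x5*x7
  x57 <- e2*x5
  x58 <- x0*x57
  x59 <- -x27*x58 + x29*x58
  x60 <- x51 - 4*x6
  x61 <- x0*x18
  x62 <- 15*x6
  x63 <- x29*x61 - x61*x62
  x64 <- x45 + x54
  x65 <- 15*x5^3
  x66 <- x10*x5
  x67 <- -x55
  x68 <- e3*x5
  x69 <- x40*x6
  x70 <- x0*x5
  x71 <- -3*e3*x10*x5*x7 + x40*x68*x7
  x72 <- -3*e3*x0*x10*x7 + x13*x62*x7
  x73 <- x45 + x69
  c(-x11*(-3*e1*x24 - e2*(e3*(-x31 - x44 - x46) + 9*x0*x10*x18 - x18*x47 + x42) + e2*(-e3*x28 + e3*x31 + x32*x38*x39 + x42 + x43) + e3*(e2*(-x30 - x46 - x48) + x10*x13*x50 - x13*x49 + x37) - e3*(-e2*x28 + e2*x30 + e2*x31 - x26 + x32*x34 + x37) - x21*x22), -x11*(e1*(e3*(-x44 - x55 - x64) - x15*x65 + 9*x15*x66 + x63) - e1*(-e3*x54 + e3*x55 + x22*x56*x60 + x43 + x63) - e3*(e1*(-x30 - x64 - x67) + e3*x50*x66 - x49*x68 + x59) + e3*(e1*x30 - e1*x54 + e1*x55 + x34*x56 - x53 + x59) + x21*x39 + x39*x52), x11*(e1*(9*e1*x0*x10*x5 - e2*(x48 + x55 + x73) - x35*x65 - x72) - e1*(3*e2*x10*x4 + 3*e2*x10*x6 - e2*x69 + x22*x60*x70 - x26 - x72) - e2*(-e1*(x31 + x67 + x73) + 9*e2*x0*x10*x5 - x47*x57 - x71) + e2*(3*e1*x10*x4 + 3*e1*x10*x6 - e1*x69 + x38*x39*x70 - x53 - x71) - x24*x33 + x33*x52))
}
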