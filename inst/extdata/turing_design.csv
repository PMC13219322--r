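item_id,stratum,truth
pair_001,2D-IA,real
pair_002,2D-IA,generated
pair_003,2D-IA,real
pair_004,2D-IA,generated
pair_005,2D-IA,real
pair_006,2D-IA,generated
pair_007,2D-IA,real
pair_008,2D-IA,generated
pair_009,2D-IA,real
pair_010,2D-IA,generated
pair_011,2D-IA,real
pair_012,2D-IA,generated
pair_013,2D-IA,real
pair_014,2D-IA,generated
pair_015,2D-IA,real
pair_016,2D-IA,generated
pair_017,2D-IA,real
pair_018,2D-IA,generated
pair_019,2D-IA,real
pair_020,2D-IA,generated
pair_021,2D-IA,real
pair_022,2D-IA,generated
pair_023,2D-IA,real
pair_024,2D-IA,generated
pair_025,2D-IA,real
pair_026,2D-IA,generated
pair_027,2D-IA,real
pair_028,2D-IA,generated
pair_029,2D-IA,real
pair_030,2D-IA,generated
pair_031,2D-IA,real
pair_032,2D-IA,generated
pair_033,2D-IA,real
pair_034,2D-IA,generated
pair_035,2D-IA,real
pair_036,2D-IA,generated
pair_037,2D-IA,real
pair_038,2D-IA,generated
pair_039,2D-IA,real
pair_040,2D-IA,generated
pair_041,2D-IA,real
pair_042,3D-IA,real
pair_043,3D-IA,generated
pair_044,3D-IA,real
pair_045,3D-IA,generated
pair_046,3D-IA,real
pair_047,3D-IA,generated
pair_048,3D-IA,real
pair_049,3D-IA,generated
pair_050,3D-IA,real
pair_051,3D-IA,generated
pair_052,3D-IA,real
pair_053,3D-IA,generated
pair_054,3D-IA,real
pair_055,3D-IA,generated
pair_056,3D-IA,real
pair_057,3D-IA,generated
pair_058,3D-IA,real
pair_059,3D-IA,generated
pair_060,3D-IA,real
pair_061,3D-IA,generated
pair_062,3D-IA,real
pair_063,3D-IA,generated
pair_064,3D-IA,real
pair_065,3D-IA,generated
pair_066,3D-IA,real
pair_067,3D-IA,generated
pair_068,3D-IA,real
pair_069,3D-IA,generated
pair_070,3D-IA,real
pair_071,3D-IA,generated
pair_072,3D-IA,real
pair_073,3D-IA,generated
pair_074,3D-IA,real
pair_075,3D-IA,generated
pair_076,3D-IA,real
pair_077,3D-IA,generated
pair_078,3D-IA,real
pair_079,3D-IA,generated
pair_080,3D-IA,real
pair_081,3D-IA,generated
pair_082,2D-CVS,real
pair_083,2D-CVS,generated
pair_084,2D-CVS,real
pair_085,2D-CVS,generated
pair_086,2D-CVS,real
pair_087,2D-CVS,generated
pair_088,2D-CVS,real
pair_089,2D-CVS,generated
pair_090,2D-CVS,real
pair_091,2D-CVS,generated
pair_092,2D-CVS,real
pair_093,2D-CVS,generated
pair_094,2D-CVS,real
pair_095,2D-CVS,generated
pair_096,2D-CVS,real
pair_097,2D-CVS,generated
pair_098,2D-CVS,real
pair_099,2D-CVS,generated
pair_100,2D-CVS,real
pair_101,2D-CVS,generated
pair_102,2D-CVS,real
pair_103,2D-CVS,generated
pair_104,2D-CVS,real
pair_105,2D-CVS,generated
pair_106,2D-CVS,real
pair_107,2D-CVS,generated
pair_108,2D-CVS,real
pair_109,2D-CVS,generated
pair_110,2D-CVS,real
pair_111,2D-CVS,generated
pair_112,3D-CVS,real
pair_113,3D-CVS,generated
pair_114,3D-CVS,real
pair_115,3D-CVS,generated
pair_116,3D-CVS,real
pair_117,3D-CVS,generated
pair_118,3D-CVS,real
pair_119,3D-CVS,generated
pair_120,3D-CVS,real
pair_121,3D-CVS,generated
pair_122,3D-CVS,real
pair_123,3D-CVS,generated
pair_124,3D-CVS,real
pair_125,3D-CVS,generated
pair_126,3D-CVS,real
pair_127,3D-CVS,generated
pair_128,3D-CVS,real
pair_129,3D-CVS,generated
pair_130,3D-CVS,real
pair_131,3D-CVS,generated
pair_132,3D-CVS,real
pair_133,3D-CVS,generated
pair_134,3D-CVS,real
pair_135,3D-CVS,generated
pair_136,3D-CVS,real
pair_137,3D-CVS,generated
pair_138,3D-CVS,real
pair_139,3D-CVS,generated
pair_140,2D-AVM,real
pair_141,2D-AVM,generated
pair_142,2D-AVM,real
pair_143,2D-AVM,generated
pair_144,2D-AVM,real
pair_145,2D-AVM,generated
pair_146,2D-AVM,real
pair_147,2D-AVM,generated
pair_148,2D-AVM,real
pair_149,2D-AVM,generated
pair_150,2D-AVM,real
pair_151,2D-AVM,generated
pair_152,2D-AVM,real
pair_153,2D-AVM,generated
pair_154,2D-AVM,real
pair_155,2D-AVM,generated
pair_156,2D-AVM,real
pair_157,3D-AVM,real
pair_158,3D-AVM,generated
pair_159,3D-AVM,real
pair_160,3D-AVM,generated
pair_161,3D-AVM,real
pair_162,3D-AVM,generated
pair_163,3D-AVM,real
pair_164,3D-AVM,generated
pair_165,3D-AVM,real
pair_166,3D-AVM,generated
pair_167,3D-AVM,real
pair_168,3D-AVM,generated
pair_169,3D-AVM,real
pair_170,3D-AVM,generated
pair_171,2D-AVF,real
pair_172,2D-AVF,generated
pair_173,2D-AVF,real
pair_174,2D-AVF,generated
pair_175,2D-AVF,real
pair_176,2D-AVF,generated
pair_177,2D-AVF,real
pair_178,2D-AVF,generated
pair_179,3D-AVF,real
pair_180,3D-AVF,generated
pair_181,3D-AVF,real
pair_182,3D-AVF,generated
pair_183,3D-AVF,real
pair_184,3D-AVF,generated
pair_185,3D-AVF,real
pair_186,3D-AVF,generated
pair_187,3D-AVF,real
pair_188,3D-AVF,generated
pair_189,3D-AVF,real
pair_190,3D-AVF,generated
pair_191,2D-MMD,real
pair_192,2D-MMD,generated
pair_193,2D-MMD,real
pair_194,2D-MMD,generated
pair_195,3D-MMD,real
pair_196,3D-MMD,generated
pair_197,3D-MMD,real
pair_198,3D-MMD,generated
pair_199,3D-MMD,real
pair_200,3D-MMD,generated
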