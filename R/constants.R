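# Physico-chemical lookup tables shared across modules.

# The 20 canonical residues, fixed column order for all emission matrices.
AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# Average (not monoisotopic) residue masses in Da, Expasy convention;
# a predicted molecular weight adds one water (18.0153 Da).
AA_MASS_AVG <- c(
  A =  71.0788, C = 103.1388, D = 115.0886, E = 129.1155, F = 147.1766,
  G =  57.0519, H = 137.1411, I = 113.1594, K = 128.1741, L = 113.1594,
  M = 131.1926, N = 114.1038, P =  97.1167, Q = 128.1307, R = 156.1875,
  S =  87.0782, T = 101.1051, V =  99.1326, W = 186.2132, Y = 163.1760)

WATER_MASS <- 18.0153

# Kyte-Doolittle hydropathy scale; range [-4.5, 4.5].
KD_SCALE <- c(
  A =  1.8, C =  2.5, D = -3.5, E = -3.5, F =  2.8,
  G = -0.4, H = -3.2, I =  4.5, K = -3.9, L =  3.8,
  M =  1.9, N = -3.5, P = -1.6, Q = -3.5, R = -4.5,
  S = -0.8, T = -0.7, V =  4.2, W = -0.9, Y = -1.3)

# Robinson-Robinson amino-acid background frequencies (optional background
# for the synthetic generators; default background is uniform).
ROBINSON_FREQS <- c(
  A = 0.0781, C = 0.0193, D = 0.0536, E = 0.0629, F = 0.0396,
  G = 0.0737, H = 0.0219, I = 0.0514, K = 0.0574, L = 0.0901,
  M = 0.0224, N = 0.0449, P = 0.0520, Q = 0.0426, R = 0.0512,
  S = 0.0712, T = 0.0584, V = 0.0644, W = 0.0132, Y = 0.0321)
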