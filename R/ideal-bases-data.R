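# Idealized nucleotide geometries in the glycosidic-N base frame
# (origin at N9/N1, x toward C1', z normal to the base plane) and
# Watson-Crick pair-placement transforms. Generated by
# tools/make_ideal_bases.py from chemical-component ideal geometry;
# do not edit by hand.

.ideal_nucleotides <- list(
  A = data.frame(
    name = c("P", "OP1", "OP2", "O5'", "C5'", "C4'", "O4'", "C3'", "O3'", "C2'", "C1'", "N9", "C8", "N7", "C5", "C6", "N6", "N1", "C2", "N3", "C4", "H5'", "H5''", "H4'", "H3'", "HO3'", "H2'", "H2''", "H1'", "H8", "H61", "H62", "H2"),
    element = c("P", "O", "O", "O", "C", "C", "O", "C", "O", "C", "C", "N", "C", "N", "C", "C", "N", "N", "C", "N", "C", "H", "H", "H", "H", "H", "H", "H", "H", "H", "H", "H", "H"),
    x = c(4.0933, 2.9157, 5.3588, 3.7743, 3.4862, 3.1724, 1.9522, 2.8559, 4.0537, 1.9915, 1.4655, 0.0000, -0.8055, -2.0545, -2.1297, -3.1807, -4.4994, -2.8797, -1.6256, -0.6088, -0.8113, 4.3504, 2.6270, 4.0021, 2.2912, 3.7848, 2.5985, 1.1622, 1.8347, -0.4590, -5.2166, -4.7063, -1.4257),
    y = c(-4.8383, -5.6265, -5.2247, -3.2687, -3.0428, -1.5619, -1.1891, -1.2869, -1.0454, -0.0068, 0.0003, 0.0000, -1.0981, -0.7331, 0.6195, 1.5513, 1.1312, 2.8459, 3.2552, 2.4199, 1.1060, -3.3252, -3.6438, -0.9412, -2.1111, -0.7913, 0.8773, -0.0606, 0.8822, -2.1205, 1.7841, 0.1829, 4.3167),
    z = c(-1.7224, -1.2961, -0.8058, -1.5639, -0.1835, 0.0372, -0.6435, 1.5288, 2.2694, 1.4456, -0.0023, 0.0000, -0.0000, 0.0010, 0.0074, 0.0023, 0.0029, 0.0024, 0.0010, 0.0001, 0.0000, 0.4184, 0.1113, -0.2997, 1.9642, 3.1620, 1.6368, 2.1523, -0.5260, -0.0004, 0.0040, -0.0006, 0.0001),
    is_base = c(FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, TRUE, TRUE, TRUE, TRUE),
    stringsAsFactors = FALSE),
  C = data.frame(
    name = c("P", "OP1", "OP2", "O5'", "C5'", "C4'", "O4'", "C3'", "O3'", "C2'", "C1'", "N1", "C2", "O2", "N3", "C4", "N4", "C5", "C6", "H5'", "H5''", "H4'", "H3'", "HO3'", "H2'", "H2''", "H1'", "H41", "H42", "H5", "H6"),
    element = c("P", "O", "O", "O", "C", "C", "O", "C", "O", "C", "C", "N", "C", "O", "N", "C", "N", "C", "C", "H", "H", "H", "H", "H", "H", "H", "H", "H", "H", "H", "H"),
    x = c(4.0962, 2.9176, 5.3592, 3.7763, 3.4864, 3.1725, 1.9540, 2.8533, 4.0509, 1.9887, 1.4647, 0.0000, -0.6687, -0.0456, -2.0004, -2.7025, -4.0776, -2.0309, -0.6776, 4.3494, 2.6263, 4.0029, 2.2885, 3.7791, 2.5960, 1.1582, 1.8356, -4.5362, -4.5881, -2.5883, -0.1412),
    y = c(3.3321, 4.2263, 4.1260, 2.0508, 2.5462, 1.3739, 0.7107, 1.8814, 2.0434, 0.7314, 0.0001, 0.0000, 1.1663, 2.2154, 1.1953, 0.0706, 0.1122, -1.1688, -1.1819, 3.0919, 3.2133, 0.6683, 2.8125, 2.2699, 0.0617, 1.1299, -1.0248, 0.9668, -0.7124, -2.0947, -2.1188),
    z = c(3.9057, 3.9327, 3.3031, 2.9836, 1.6766, 0.7447, 1.1486, -0.6839, -1.4472, -1.2517, -0.0002, 0.0000, -0.0000, 0.0004, 0.0006, 0.0011, 0.0023, 0.0052, 0.0000, 1.2949, 1.7214, 0.7246, -0.6487, -2.3478, -1.8595, -1.8354, 0.0119, 0.0030, -0.0020, 0.0053, -0.0013),
    is_base = c(FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, TRUE, TRUE, TRUE, TRUE),
    stringsAsFactors = FALSE),
  G = data.frame(
    name = c("P", "OP1", "OP2", "O5'", "C5'", "C4'", "O4'", "C3'", "O3'", "C2'", "C1'", "N9", "C8", "N7", "C5", "C6", "O6", "N1", "C2", "N2", "N3", "C4", "H5'", "H5''", "H4'", "H3'", "HO3'", "H2'", "H2''", "H1'", "H8", "H1", "H21", "H22"),
    element = c("P", "O", "O", "O", "C", "C", "O", "C", "O", "C", "C", "N", "C", "N", "C", "C", "O", "N", "C", "N", "N", "C", "H", "H", "H", "H", "H", "H", "H", "H", "H", "H", "H", "H"),
    x = c(4.0952, 2.9170, 5.3580, 3.7762, 3.4862, 3.1723, 1.9534, 2.8528, 4.0505, 1.9881, 1.4640, 0.0000, -0.8066, -2.0552, -2.1236, -3.1870, -4.3466, -2.8849, -1.5856, -1.3092, -0.5889, -0.8091, 4.3488, 2.6252, 4.0024, 2.2870, 3.7789, 2.5957, 1.1584, 1.8349, -0.4611, -3.5979, -0.3889, -2.0343),
    y = c(-4.8404, -5.6281, -5.2259, -3.2702, -3.0438, -1.5627, -1.1901, -1.2865, -1.0450, -0.0063, -0.0006, 0.0000, -1.0999, -0.7320, 0.6216, 1.5544, 1.1789, 2.8709, 3.2793, 4.6230, 2.4228, 1.1032, -3.3258, -3.6441, -0.9417, -2.1101, -0.7898, 0.8782, -0.0599, 0.8810, -2.1237, 3.5290, 4.9289, 5.2676),
    z = c(-1.7117, -1.2874, -0.7937, -1.5553, -0.1753, 0.0438, -0.6388, 1.5351, 2.2774, 1.4496, 0.0011, 0.0000, -0.0000, -0.0012, -0.0020, -0.0033, -0.0041, 0.0036, -0.0016, -0.0024, -0.0017, -0.0000, 0.4275, 0.1191, -0.2917, 1.9708, 3.1691, 1.6397, 2.1544, -0.5225, 0.0004, 0.0023, -0.0019, -0.0074),
    is_base = c(FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, TRUE, TRUE, TRUE, TRUE),
    stringsAsFactors = FALSE),
  T = data.frame(
    name = c("P", "OP1", "OP2", "O5'", "C5'", "C4'", "O4'", "C3'", "O3'", "C2'", "C1'", "N1", "C2", "O2", "N3", "C4", "O4", "C5", "C7", "C6", "H5'", "H5''", "H4'", "H3'", "HO3'", "H2'", "H2''", "H1'", "H3", "H71", "H72", "H73", "H6"),
    element = c("P", "O", "O", "O", "C", "C", "O", "C", "O", "C", "C", "N", "C", "O", "N", "C", "O", "C", "C", "C", "H", "H", "H", "H", "H", "H", "H", "H", "H", "H", "H", "H", "H"),
    x = c(1.2213, 0.8860, 2.2703, 1.9055, 2.2514, 2.8746, 1.8808, 3.2724, 4.3301, 2.0192, 1.4337, 0.0000, -0.7019, -0.1548, -2.0957, -2.8349, -4.0623, -2.0260, -2.7501, -0.6908, 1.3498, 2.9627, 3.7153, 3.6168, 5.0410, 1.3393, 2.2014, 1.7902, -2.6221, -3.3715, -2.0318, -3.3789, -0.0632),
    y = c(-5.4242, -6.2030, -6.1438, -3.9812, -3.1827, -1.8843, -1.1833, -0.9478, -0.0922, -0.1349, -0.0354, 0.0000, 1.2244, 2.3287, 1.1080, -0.0653, -0.0952, -1.3133, -2.6212, -1.2051, -2.9742, -3.7323, -2.1127, -1.4701, -0.1590, -0.6817, 0.8536, 0.8594, 1.9767, -2.6963, -3.4404, -2.6932, -2.0914),
    z = c(-0.3205, -1.5588, 0.6766, -0.5845, 0.5347, 0.0395, -0.7331, 1.1717, 0.7451, 1.3999, 0.0008, 0.0000, 0.0000, -0.0002, -0.0002, -0.0011, -0.0025, -0.0001, 0.0001, -0.0000, 1.1149, 1.1564, -0.6229, 2.0688, 1.4062, 2.0644, 1.8331, -0.5209, -0.0007, 0.8909, -0.0092, -0.8869, 0.0003),
    is_base = c(FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, TRUE, TRUE, TRUE, TRUE, TRUE),
    stringsAsFactors = FALSE)
)

.wc_pair_transforms <- list(
  A = list(R = matrix(c(-0.99724325, -0.07420176, 0.00000000, -0.07420176, 0.99724325, 0.00000000, 0.00000000, 0.00000000, -1.00000000), 3, 3), t = c(-7.01337799, 3.43820883, 0.00000000)),
  C = list(R = matrix(c(0.24525062, 0.96945971, 0.00000000, 0.96945971, -0.24525062, 0.00000000, 0.00000000, 0.00000000, -1.00000000), 3, 3), t = c(-7.00651251, 5.15337748, 0.00000000)),
  G = list(R = matrix(c(0.25689491, 0.96643934, 0.00000000, 0.96643934, -0.25689491, 0.00000000, 0.00000000, 0.00000000, -1.00000000), 3, 3), t = c(-6.22466714, 6.04558229, 0.00000000)),
  T = list(R = matrix(c(-0.99724325, -0.07420176, 0.00000000, -0.07420176, 0.99724325, 0.00000000, 0.00000000, 0.00000000, -1.00000000), 3, 3), t = c(-6.73892273, -3.94913551, 0.00000000))
)
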