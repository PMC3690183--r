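# Frozen quantile table for the Tracy-Widom TW1 distribution,
# generated by tools/make-tw-table.R (Painleve II integration).
# .tw1_s: support grid; .tw1_logp: log upper-tail probability log(1 - F1(s)).
.tw1_s <- seq(-5, 8, by = 0.02)
.tw1_logp <- c(-0.00025662046, -0.00027885073, -0.00030275358, -0.00032843848, -0.00035602095, -0.00038562278, -0.00041737234, -0.00045140479, -0.00048786243, -0.00052689489, -0.00056865948, -0.00061332146, -0.00066105431, -0.00071204007, -0.0007664696, -0.00082454291, -0.00088646946, -0.00095246847, -0.0010227692, -0.0010976114, -0.0011772455, -0.0012619327, -0.001351946, -0.0014475696, -0.0015491001, -0.001656846, -0.0017711286, -0.0018922822, -0.002020654, -0.0021566052, -0.0023005104, -0.0024527584, -0.0026137527, -0.0027839112, -0.0029636667, -0.0031534675, -0.0033537773, -0.0035650754, -0.0037878572, -0.0040226343, -0.0042699347, -0.004530303, -0.0048043007, -0.0050925062, -0.005395515, -0.0057139402, -0.0060484121, -0.0063995786, -0.0067681052, -0.0071546755, -0.0075599905, -0.0079847693, -0.0084297488, -0.008895684, -0.0093833476, -0.0098935303, -0.010427041, -0.010984705, -0.011567368, -0.01217589, -0.012811151, -0.013474047, -0.014165492, -0.014886416, -0.015637767, -0.016420509, -0.017235622, -0.018084103, -0.018966962, -0.019885229, -0.020839945, -0.021832167, -0.022862969, -0.023933435, -0.025044666, -0.026197774, -0.027393885, -0.028634137, -0.02991968, -0.031251675, -0.032631295, -0.034059724, -0.035538153, -0.037067786, -0.038649833, -0.040285515, -0.041976058, -0.043722698, -0.045526677, -0.047389241, -0.049311644, -0.051295145, -0.053341006, -0.055450494, -0.057624877, -0.05986543, -0.062173425, -0.064550139, -0.066996849, -0.069514831, -0.072105362, -0.074769718, -0.077509174, -0.080325, -0.083218468, -0.086190843, -0.089243389, -0.092377363, -0.095594019, -0.098894606, -0.10228037, -0.10575253, -0.10931234, -0.11296101, -0.11669975, -0.12052977, -0.12445226, -0.12846842, -0.13257942, -0.13678643, -0.1410906, -0.14549309, -0.14999502, -0.15459753, -0.15930172, -0.16410869, -0.16901952, -0.1740353, -0.17915708, -0.1843859, -0.18972281, -0.19516882, -0.20072492, -0.20639213, -0.2121714, -0.21806369, -0.22406997, -0.23019114, -0.23642813, -0.24278183, -0.24925313, -0.25584289, -0.26255197, -0.26938119, -0.27633138, -0.28340334, -0.29059785, -0.29791569, -0.3053576, -0.31292432, -0.32061658, -0.32843506, -0.33638047, -0.34445347, -0.35265472, -0.36098485, -0.36944448, -0.37803422, -0.38675465, -0.39560636, -0.40458988, -0.41370577, -0.42295455, -0.43233673, -0.44185279, -0.45150321, -0.46128846, -0.47120898, -0.4812652, -0.49145753, -0.50178638, -0.51225212, -0.52285514, -0.53359577, -0.54447437, -0.55549126, -0.56664676, -0.57794115, -0.58937473, -0.60094776, -0.61266051, -0.62451321, -0.63650609, -0.64863938, -0.66091328, -0.67332797, -0.68588365, -0.69858047, -0.71141858, -0.72439815, -0.73751928, -0.75078211, -0.76418674, -0.77773327, -0.79142179, -0.80525236, -0.81922506, -0.83333994, -0.84759704, -0.8619964, -0.87653804, -0.89122197, -0.9060482, -0.92101673, -0.93612753, -0.9513806, -0.96677589, -0.98231337, -0.99799298, -1.0138147, -1.0297784, -1.045884, -1.0621316, -1.0785209, -1.0950518, -1.1117244, -1.1285384, -1.1454938, -1.1625903, -1.179828, -1.1972067, -1.2147262, -1.2323863, -1.2501869, -1.268128, -1.2862092, -1.3044304, -1.3227914, -1.3412922, -1.3599324, -1.3787118, -1.3976304, -1.4166878, -1.435884, -1.4552186, -1.4746914, -1.4943023, -1.514051, -1.5339373, -1.553961, -1.5741217, -1.5944194, -1.6148537, -1.6354245, -1.6561314, -1.6769742, -1.6979526, -1.7190665, -1.7403155, -1.7616995, -1.783218, -1.8048709, -1.8266579, -1.8485787, -1.8706331, -1.8928207, -1.9151414, -1.9375948, -1.9601806, -1.9828986, -2.0057485,  -2.02873, -2.0518428, -2.0750867, -2.0984613, -2.1219663, -2.1456015, -2.1693666, -2.1932613, -2.2172853, -2.2414383,  -2.26572, -2.2901301, -2.3146683, -2.3393343, -2.3641279, -2.3890487, -2.4140964, -2.4392708, -2.4645715, -2.4899982, -2.5155507, -2.5412286, -2.5670317, -2.5929596, -2.619012, -2.6451888, -2.6714894, -2.6979138, -2.7244614, -2.7511322, -2.7779257, -2.8048417, -2.8318798, -2.8590398, -2.8863214, -2.9137243, -2.9412482, -2.9688927, -2.9966577, -3.0245428, -3.0525477, -3.0806721, -3.1089157, -3.1372783, -3.1657595, -3.1943591, -3.2230768, -3.2519123, -3.2808652, -3.3099354, -3.3391225, -3.3684263, -3.3978464, -3.4273825, -3.4570345, -3.486802, -3.5166848, -3.5466824, -3.5767948, -3.6070216, -3.6373625, -3.6678172, -3.6983856, -3.7290672, -3.7598618, -3.7907693, -3.8217892, -3.8529213, -3.8841654, -3.9155212, -3.9469884, -3.9785667, -4.010256, -4.0420558, -4.0739661, -4.1059864, -4.1381167, -4.1703565, -4.2027056, -4.2351638, -4.2677309, -4.3004065, -4.3331904, -4.3660824, -4.3990822, -4.4321896, -4.4654043, -4.4987261, -4.5321547, -4.5656899, -4.5993315, -4.6330791, -4.6669326, -4.7008917, -4.7349563, -4.7691259, -4.8034004, -4.8377797, -4.8722633, -4.9068512, -4.941543, -4.9763386, -5.0112377, -5.0462401, -5.0813455, -5.1165537, -5.1518646, -5.1872778, -5.2227932, -5.2584105, -5.2941296, -5.3299501, -5.3658719, -5.4018948, -5.4380185, -5.4742429, -5.5105676, -5.5469926, -5.5835175, -5.6201422, -5.6568665, -5.6936901, -5.7306129, -5.7676346, -5.8047551, -5.8419741, -5.8792914, -5.9167068, -5.9542202, -5.9918312, -6.0295399, -6.0673458, -6.1052488, -6.1432488, -6.1813455, -6.2195388, -6.2578284, -6.2962141, -6.3346958, -6.3732733, -6.4119463, -6.4507147, -6.4895784, -6.528537, -6.5675905, -6.6067386, -6.6459812, -6.685318, -6.724749, -6.7642738, -6.8038924, -6.8436045,  -6.88341, -6.9233087, -6.9633004, -7.0033849, -7.0435621, -7.0838318, -7.1241938, -7.1646479, -7.205194, -7.2458319, -7.2865615, -7.3273825, -7.3682947, -7.4092981, -7.4503925, -7.4915776, -7.5328534, -7.5742196, -7.6156761, -7.6572227, -7.6988593, -7.7405857, -7.7824017, -7.8243072, -7.8663021, -7.9083861, -7.9505591, -7.992821, -8.0351716, -8.0776107, -8.1201381, -8.1627538, -8.2054576, -8.2482493, -8.2911288, -8.3340959, -8.3771505, -8.4202924, -8.4635214, -8.5068375, -8.5502404, -8.5937301, -8.6373064, -8.6809691, -8.724718, -8.7685531, -8.8124742, -8.8564812, -8.9005739, -8.9447521, -8.9890158, -9.0333648, -9.0777989, -9.122318, -9.166922, -9.2116108, -9.2563841, -9.3012419, -9.346184, -9.3912102, -9.4363206, -9.4815148, -9.5267929, -9.5721546, -9.6175997, -9.6631283, -9.7087402, -9.7544351, -9.800213, -9.8460738, -9.8920174, -9.9380435, -9.9841521, -10.030343, -10.076616, -10.122971, -10.169409, -10.215928, -10.262529, -10.309211, -10.355975, -10.40282, -10.449746, -10.496754, -10.543842, -10.591011, -10.638262, -10.685592, -10.733003, -10.780495, -10.828067, -10.875718, -10.92345, -10.971262, -11.019154, -11.067125, -11.115176, -11.163306, -11.211516, -11.259804, -11.308172, -11.356619, -11.405145, -11.453749, -11.502432, -11.551194, -11.600034, -11.648952, -11.697949, -11.747023, -11.796176, -11.845406, -11.894714,  -11.9441, -11.993563, -12.043104, -12.092722, -12.142418, -12.19219, -12.242039, -12.291966, -12.341969, -12.392048, -12.442205, -12.492438, -12.542747, -12.593132, -12.643594, -12.694132, -12.744745, -12.795435,  -12.8462, -12.897041, -12.947957, -12.998949, -13.050017, -13.101159, -13.152377, -13.20367, -13.255038, -13.30648, -13.357998, -13.40959, -13.461256, -13.512997, -13.564813, -13.616703, -13.668666, -13.720704, -13.772816, -13.825002, -13.877262, -13.929596, -13.982003, -14.034483, -14.087037, -14.139665, -14.192365, -14.245139, -14.297986, -14.350906, -14.403899, -14.456964, -14.510102, -14.563313, -14.616596, -14.669952, -14.72338, -14.776881, -14.830453, -14.884098, -14.937815, -14.991603, -15.045464, -15.099396, -15.153399, -15.207475, -15.261622, -15.31584, -15.370129, -15.42449, -15.478922, -15.533425, -15.587998, -15.642643, -15.697359, -15.752145, -15.807002, -15.861929, -15.916927, -15.971995, -16.027134, -16.082342, -16.137621, -16.19297, -16.248389, -16.303878, -16.359437, -16.415065, -16.470763, -16.526531, -16.582368, -16.638274, -16.69425, -16.750295, -16.806409, -16.862593, -16.918845, -16.975166, -17.031557, -17.088016, -17.144543, -17.20114, -17.257805, -17.314538, -17.37134, -17.42821, -17.485148, -17.542155, -17.59923, -17.656372, -17.713583, -17.770862, -17.828208, -17.885622, -17.943104, -18.000653, -18.05827, -18.115954, -18.173706, -18.231525, -18.289411, -18.347365, -18.405385, -18.463472, -18.521627, -18.579848, -18.638136)
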