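# 20 diffusion directions (unit vectors, one per row: x y z)
# spherical Fibonacci lattice polished by electrostatic repulsion
# fixture version 1 - do not regenerate
0.499636876373 -0.864258552798 0.058482011626
-0.887942618329 0.412107647056 0.204267456518
0.930853827926 0.318285336634 0.179459175074
-0.574640748172 -0.795408323229 0.192648929086
0.046354959464 0.986840908930 0.154907192199
0.835385953379 -0.454370252645 0.309318577534
-0.949768244718 -0.126999211412 0.286027064498
0.602612165286 0.719546063400 0.345126123171
-0.014435573719 -0.929297080830 0.369050876943
-0.480630264968 0.720154512569 0.500371888122
0.809214110475 -0.020385877462 0.587160062852
-0.657215252353 -0.451364064244 0.603604666636
0.095106186377 0.771516710364 0.629060234748
0.432006972320 -0.625077597304 0.650113815586
-0.678935204954 0.191782804516 0.708707516092
0.479638482351 0.368291195676 0.796434882106
-0.137465764428 -0.615859394088 0.775770823326
-0.132654672372 0.382630563067 0.914328491356
0.314680546720 -0.150691644028 0.937159635247
-0.269473170190 -0.128757675233 0.954361394659
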