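# Built-in material definitions: elemental mass fractions and default mass
# densities (g/cm^3). Fractions are computed from standard atomic masses
# (H 1.008, C 12.011, N 14.007, O 15.999, Al 26.9815385, Si 28.085).
water:
  density: 1.000
  composition: {H: 0.1119067, O: 0.8880933}
graphite:
  density: 1.700
  composition: {C: 1.0}
aluminum:
  density: 2.699
  composition: {Al: 1.0}
silicon:
  density: 2.330
  composition: {Si: 1.0}
pmma:
  density: 1.190
  composition: {H: 0.0805458, C: 0.5998482, O: 0.3196060}
pe:
  density: 0.930
  composition: {H: 0.1437228, C: 0.8562772}
vacuum:
  density: 0.0
  composition: {H: 1.0}
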