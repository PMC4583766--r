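metabolites:
- id: S
  atoms: 3
  boundary: yes
  conc: 1.0
- id: A
  atoms: 3
  boundary: no
  conc: 0.5
- id: B
  atoms: 3
  boundary: no
  conc: 0.5
- id: C
  atoms: 1
  boundary: no
  conc: 0.20000000000000001
- id: D
  atoms: 2
  boundary: no
  conc: 0.20000000000000001
- id: E
  atoms: 3
  boundary: no
  conc: 0.29999999999999999
reactions:
- id: v1
  atoms: S(abc) -> A(abc)
  forward: Vmax1 * S/(Km1 + S)
- id: v2
  atoms: A(abc) -> B(acb)
  forward: Vmax2 * A/(Km2 + A)
- id: v3
  atoms: B(abc) -> C(a) + D(bc)
  forward: k3f * B
  backward: k3b * C * D
- id: v4
  atoms: B(abc) -> E(abc)
  forward: Vmax4 * B/(Km4 + B)
- id: v5
  atoms: C(a) -> SINK_C(a)
  forward: Vmax5 * C/(Km5 + C)
- id: v6
  atoms: D(ab) -> SINK_D(ab)
  forward: Vmax6 * D/(Km6 + D)
- id: v7
  atoms: E(abc) -> SINK_E(abc)
  forward: Vmax7 * E/(Km7 + E)
parameters:
  Vmax1: 2.0
  Km1: 1.0
  Vmax2: 3.0
  Km2: 1.0
  k3f: 4.0
  k3b: 8.0
  Vmax4: 2.0
  Km4: 1.0
  Vmax5: 2.0
  Km5: 0.5
  Vmax6: 2.0
  Km6: 0.5
  Vmax7: 2.0
  Km7: 1.0
kie:
- reaction: v2
  metabolite: A
  pattern: '100'
  alpha: 0.97999999999999998
- reaction: v2
  metabolite: A
  pattern: '010'
  alpha: 0.96999999999999997
- reaction: v3
  metabolite: B
  pattern: '100'
  alpha: 0.98499999999999999
- reaction: v3
  metabolite: C
  pattern: '1'
  alpha: 0.98999999999999999
- reaction: v3
  metabolite: D
  pattern: '10'
  alpha: 0.995
- reaction: v4
  metabolite: B
  pattern: '001'
  alpha: 0.98999999999999999
- reaction: v5
  metabolite: C
  pattern: '1'
  alpha: 0.98199999999999998
label_input:
  S:
    '100': 0.80000000000000004
    '111': 0.20000000000000001
natural_abundance: 0.0107
exchange: yes
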