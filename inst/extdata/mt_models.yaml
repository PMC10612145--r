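# Bundled registry of stepwise Zn(II) binding models for ten
# metallothioneins (animal: BcrMT1B, LlMT, SpMTA, XlMT; plant: MacMT3,
# OsMTI-1B, Ec-1; bacterial: PflQ2MT, SmtA, TvMT), together with the
# probes and chelators used in competition experiments. All constants
# are apparent (conditional) -log10 molar values at pH 7.4; groups
# expand tightest-first into one identical step constant per site.
#
# pka_prime is the apparent average thiol pKa from UV-monitored pH
# titrations of the Zn(II)-loaded protein (used as simulation truth).
#
# The PflQ2MT tight-site constant is a SYNTHETIC estimate: its CD
# competition gave no usable signal, so the mean of the two measured
# bacterial metal-buffer constants (14.68, 14.3) is used as a stand-in
# for its "low femtomolar" sites.
proteins:
  - name: BcrMT1B
    pka_prime: 4.97
    groups:
      tight: {count: 3, pkd: 11.5}
      moderate: [10.5, 9.80]
      weak: [8.03]
  - name: LlMT
    pka_prime: 4.83
    groups:
      tight: {count: 4, pkd: 11.5}
      moderate: [10.9, 10.0]
      weak: {count: 3, pkd: 6.75}
    weak_release: cooperative
  - name: SpMTA
    pka_prime: 4.94
    groups:
      tight: [11.5, 11.5, 11.5, 11.2]
      moderate: [10.5, 9.31]
      weak: [8.54]
  - name: XlMT
    pka_prime: 4.73
    groups:
      tight: {count: 4, pkd: 11.2}
      moderate: [10.1, 9.37]
      weak: [7.74]
  - name: MacMT3
    pka_prime: 4.97
    pkd_steps: [11.4, 9.9, 8.81]
  - name: OsMTI-1B
    pka_prime: 5.04
    groups:
      tight: [11.7]
      moderate: [10.1]
      weak: {count: 2, pkd: 7.76}
  - name: Ec-1
    pka_prime: 4.44
    groups:
      tight: {count: 3, pkd: 11.1}
      moderate: [10.8, 9.58]
      weak: [7.96]
  - name: PflQ2MT
    pka_prime: 4.75
    groups:
      tight: {count: 2, pkd: 14.49}   # synthetic estimate, see header
      weak: [10.3]
  - name: SmtA
    pka_prime: 4.29
    groups:
      tight: {count: 2, pkd: 14.68}
      moderate: [12.9]
      weak: [11.2]
  - name: TvMT
    pka_prime: 4.19
    groups:
      tight: {count: 2, pkd: 14.3}
      moderate: [12.6]
      weak: [10.9]
chelators:
  - {name: ATP, pkd: 5.1}
  - {name: triphosphate, pkd: 6.9}
  - {name: NTA, pkd: 8.4}
  - {name: HEDTA, kd: 6.6e-13}
  - {name: EDTA, kd: 2.3e-14}
  - {name: TPEN, kd: 6.4e-16}
probes:
  par: {name: PAR, kd12: 7.1e-13, epsilon_492: 71500, path_length: 1}
  znaf: {name: ZnAF-2F, kd: 5.5e-9}
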