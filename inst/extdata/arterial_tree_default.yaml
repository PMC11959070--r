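# svpulse reduced systemic arterial tree (config schema version 1).
#
# A nine-segment reduction covering the aortic root -> iliac/femoral path
# plus common carotid and subclavian/brachial branches. All values are
# package defaults (synthetic): geometry and Windkessel parameters were
# chosen once so the reference state (CO 5.5 L/min, HR 75 bpm, ET 0.23 s)
# yields physiological brachial pressures. Units: lengths/diameters cm,
# distensibility 1e-3/mmHg, resistances mmHg.s/mL, compliances mL/mmHg,
# pressures mmHg. The parallel combination of terminal resistances is
# exactly 1.0 mmHg.s/mL.
version: 1
reference:
  pressure_mmhg: 90
  aortic_distensibility: 7.8
  height_cm: 180
segments:
  - id: ascending_aorta
    parent: ~
    length_cm: 5
    din_cm: 2.9
    dout_cm: 2.7
    distensibility: 7.8
  - id: common_carotid
    parent: ascending_aorta
    length_cm: 15
    din_cm: 0.8
    dout_cm: 0.7
    distensibility: 6.0
  - id: subclavian_brachial
    parent: ascending_aorta
    length_cm: 42
    din_cm: 0.9
    dout_cm: 0.5
    distensibility: 5.0
  - id: thoracic_aorta
    parent: ascending_aorta
    length_cm: 16
    din_cm: 2.7
    dout_cm: 2.2
    distensibility: 7.8
  - id: abdominal_aorta
    parent: thoracic_aorta
    length_cm: 8
    din_cm: 2.2
    dout_cm: 1.9
    distensibility: 7.0
  - id: visceral_trunk
    parent: abdominal_aorta
    length_cm: 6
    din_cm: 0.9
    dout_cm: 0.7
    distensibility: 5.0
  - id: infrarenal_aorta
    parent: abdominal_aorta
    length_cm: 8
    din_cm: 1.9
    dout_cm: 1.6
    distensibility: 6.0
  - id: left_iliac_femoral
    parent: infrarenal_aorta
    length_cm: 22
    din_cm: 1.0
    dout_cm: 0.7
    distensibility: 5.0
  - id: right_iliac_femoral
    parent: infrarenal_aorta
    length_cm: 22
    din_cm: 1.0
    dout_cm: 0.7
    distensibility: 5.0
terminals:
  - segment: common_carotid
    r1: 0.8
    r2: 9.2
    c: 0.08
    pout: 0
  - segment: subclavian_brachial
    r1: 0.9
    r2: 9.1
    c: 0.08
    pout: 0
  - segment: visceral_trunk
    r1: 0.2
    r2: 2.3
    c: 0.35
    pout: 0
  - segment: left_iliac_femoral
    r1: 0.7
    r2: 4.3
    c: 0.17
    pout: 0
  - segment: right_iliac_femoral
    r1: 0.7
    r2: 4.3
    c: 0.17
    pout: 0
sites:
  - site: aortic_root
    segment: ascending_aorta
    position: 0
  - site: carotid
    segment: common_carotid
    position: 0.1
  - site: left_brachial
    segment: subclavian_brachial
    position: 0.9
  - site: femoral
    segment: left_iliac_femoral
    position: 0.95
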