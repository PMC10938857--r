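disorders:
- name: alcohol-use disorder
  icd10:
  - F10
  earliest_onset_age: 12.0
- name: opioid-use disorder
  icd10:
  - F11
  earliest_onset_age: 12.0
- name: cannabis-use disorder
  icd10:
  - F12
  earliest_onset_age: 10.0
- name: cocaine-use disorder
  icd10:
  - F14
  earliest_onset_age: 12.0
- name: amphetamine-use disorder
  icd10:
  - F15
  earliest_onset_age: 10.0
- name: other drug-use disorders
  icd10:
  - F13
  - F16
  - F18
  - F19
  earliest_onset_age: 10.0
- name: schizophrenia
  icd10:
  - F20
  earliest_onset_age: 10.0
- name: bipolar disorder
  icd10:
  - F30
  - F31
  earliest_onset_age: 10.0
- name: major depressive disorder
  icd10:
  - F32
  - F33
  earliest_onset_age: 5.0
- name: dysthymia
  icd10:
  - F34.1
  earliest_onset_age: 5.0
- name: anxiety disorders
  icd10:
  - F40
  - F41
  earliest_onset_age: 3.0
- name: anorexia nervosa
  icd10:
  - F50.0
  - F50.1
  earliest_onset_age: 5.0
- name: bulimia nervosa
  icd10:
  - F50.2
  - F50.3
  earliest_onset_age: 8.0
- name: personality disorders
  icd10:
  - F60
  - F61
  earliest_onset_age: 12.0
- name: intellectual disabilities
  icd10:
  - F70
  - F71
  - F72
  - F73
  - F78
  - F79
  earliest_onset_age: 0.0
- name: autism spectrum disorders
  icd10:
  - F84
  earliest_onset_age: 1.0
- name: ADHD
  icd10:
  - F90
  earliest_onset_age: 3.0
- name: conduct disorders
  icd10:
  - F91
  earliest_onset_age: 2.0
- name: any mental disorder
  icd10:
  - F10
  - F11
  - F12
  - F13
  - F14
  - F15
  - F16
  - F18
  - F19
  - F20
  - F30
  - F31
  - F32
  - F33
  - F34.1
  - F40
  - F41
  - F50.0
  - F50.1
  - F50.2
  - F50.3
  - F60
  - F61
  - F70
  - F71
  - F72
  - F73
  - F78
  - F79
  - F84
  - F90
  - F91
  earliest_onset_age: 0.0
  aggregate: yes
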