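indicator,response,traditions,emergencies,recognition,resources,health_systems,inevitability
_prior,,0.1666667,0.1666667,0.1666667,0.1666667,0.1666667,0.1666667
Id10450,yes,0.3,0.2,0.3,0.3,0.9,0.5
Id10450,no,0.7,0.8,0.7,0.7,0.1,0.5
Id10451,yes,0.3,0.2,0.3,0.15,0.8,0.5
Id10451,no,0.7,0.8,0.7,0.85,0.2,0.5
Id10452,yes,0.1,0.1,0.1,0.1,0.7,0.1
Id10452,no,0.9,0.9,0.9,0.9,0.3,0.9
Id10453,yes,0.1,0.1,0.1,0.1,0.7,0.1
Id10453,no,0.9,0.9,0.9,0.9,0.3,0.9
Id10454,yes,0.1,0.1,0.1,0.1,0.7,0.1
Id10454,no,0.9,0.9,0.9,0.9,0.3,0.9
Id10455,yes,0.2,0.2,0.2,0.8,0.2,0.2
Id10455,no,0.8,0.8,0.8,0.2,0.8,0.8
Id10456,yes,0.3,0.2,0.85,0.2,0.1,0.2
Id10456,no,0.7,0.8,0.15,0.8,0.9,0.8
Id10457,yes,0.9,0.1,0.3,0.2,0.1,0.2
Id10457,no,0.1,0.9,0.7,0.8,0.9,0.8
Id10458,yes,0.5,0.3,0.4,0.2,0.7,0.5
Id10458,no,0.5,0.7,0.6,0.8,0.3,0.5
Id10459,yes,0.4,0.2,0.3,0.85,0.4,0.3
Id10459,no,0.6,0.8,0.7,0.15,0.6,0.7
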