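{"total":{"A32":[1,2,3],"A21":[1,2,3],"A9":[1,2,3],"A17":[1,2,3],"A4":[1,2,3,4],"C16":[1,2,3],"B8":[1,2,3],"A20":[1,2,3],"C23":[1,2,3],"B7":[1,2,3],"A33":[1,2,3],"C21":[1,2,3],"A2":[1,2,3],"A22":[1,2,3,4],"A30":[1,2,3],"C24":[1,2,3],"A28":[1,2,3]},"ESF":{"A32":[1,2,3],"A21":[1,2,3],"A9":[1,2,3],"A17":[1,2,3],"A4":[1,2,3,4],"C16":[1,2,3],"B8":[1,2,3],"A20":[1,2,3],"C23":[1,2,3],"B7":[1,2,3],"A33":[1,2,3]},"ISF":{"C21":[1,2,3],"A2":[1,2,3],"A22":[1,2,3,4],"A30":[1,2,3],"C24":[1,2,3],"A28":[1,2,3]}}
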