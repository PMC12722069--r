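term,path,offset,is_family,is_spouse_partner
ego,,0,1,0
father,P,1,1,0
mother,P,1,1,0
parent,P,1,1,0
grandparent,PP,2,1,0
grandaunt_uncle,PPS,2,1,0
sibling,S,0,1,0
aunt_uncle,PS,1,1,0
godparent,,1,1,0
cousin,PSC,0,1,0
child,C,-1,1,0
niece_nephew,SC,-1,1,0
grandchild,CC,-2,1,0
spouse_partner,M,0,1,1
parent_in_law,MP,1,1,0
sibling_in_law,MS,0,1,0
child_in_law,CM,-1,1,0
friend,,NA,0,0
other,,NA,0,0
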