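>synth01
GSGSCAVSNLTSTRSLYNSVFNQIFSHYGFFNFAVSMPSSLGLNVQDSATYYFSMVMNGYFGCTLGPR
>synth02
GSGSCFTKVLMQRGQMSRIFMGTVKHMYIGMFLPTYTVPRQAMNYNHTRVYSFPQHHNAGQVCTLGPR
>synth03
GSGSCSGGTPNQQGAQAIGKITFSFPAMAMSEHKAVAFRNATESQINMKQMYVQVEFHLVDYCTLGPR
>synth04
GSGSCDVRATITAPQMKPDFAGPNSQKIRKSRRENTLRAHIVQKYNLVNIYYISYFPIPMSVCTLGPR
>synth05
GSGSCQKQREGHEVRSDLILHREKGAHKQTYQTQPVLYVPFFNHDDDPYVPIQKTIPMPAFTCTLGPR
>synth06
GSGSCSDFHPAGGYIQGNNISFQYKDTRKLVPKDYMGDFVGALILMRLDKKKTRIKFGRLTECTLGPR
>synth07
GSGSCHINRKNKDPPKQPVNMPKVKFDEILPQIFHRITYDFGHTKDVPHNDRKLTDTEEEQACTLGPR
>synth08
GSGSCVVFTNRAPHKIKERRNDNLDSEKKQNKDASQVTIKEALSYEFEKKKDQLRRQIMNPICTLGPR
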